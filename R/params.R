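#' Cell-specific IMK parameter set
#'
#' Bundles the parameters of the integrated microdosimetric-kinetic (IMK)
#' model for one cell line. Two overlapping subsets are used downstream:
#' `(k_N, a, b, a_plus_c, gamma)` drives the lesion-kinetics predictions and
#' `(alpha0, beta0, a_plus_c, gamma)` the survival predictions. The two are
#' linked by `alpha0 = a k_N / (a + c)` and `beta0 = b k_N^2 / (2 (a + c))`;
#' when `a` and `b` are not supplied they are derived from those relations so
#' the set is exactly self-consistent.
#'
#' @param k_N initial double-strand-break (PLL) yield per nucleus per Gy.
#' @param a_plus_c total PLL removal rate (conversion + repair), per hour.
#' @param alpha0 linear survival coefficient, per Gy.
#' @param beta0 quadratic survival coefficient, per Gy^2.
#' @param gamma microdosimetric single-event dose factor, Gy.
#' @param a first-order PLL-to-lethal-lesion conversion rate, per hour
#'   (derived from `alpha0` if missing).
#' @param b nucleus-level second-order PLL-pair conversion rate, per hour
#'   (derived from `beta0` if missing).
#' @param sd optional named list of standard deviations for any of the fields.
#' @param cell_line label.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(k_N, a_plus_c, alpha0, beta0, gamma,
                        a = NULL, b = NULL, sd = list(), cell_line = "cell") {
  vals <- c(k_N = k_N, a_plus_c = a_plus_c, alpha0 = alpha0,
            beta0 = beta0, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("k_N, a_plus_c, alpha0, beta0 and gamma must all be positive")
  derived <- alpha0_beta0_from_micro(
    k_N = k_N,
    a = if (is.null(a)) alpha0 * a_plus_c / k_N else a,
    b = if (is.null(b)) 2 * beta0 * a_plus_c / k_N^2 else b,
    a_plus_c = a_plus_c
  )
  if (is.null(a)) a <- alpha0 * a_plus_c / k_N
  if (is.null(b)) b <- 2 * beta0 * a_plus_c / k_N^2
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  if (a >= a_plus_c) stop("a must be smaller than a_plus_c (repair rate c > 0)")
  # printed parameter tables are rounded; tolerate a few percent of drift
  if (abs(derived[["alpha0"]] - alpha0) / alpha0 > 0.05)
    warning("alpha0 is inconsistent with a*k_N/(a+c) by more than 5%")
  if (abs(derived[["beta0"]] - beta0) / beta0 > 0.05)
    warning("beta0 is inconsistent with b*k_N^2/(2(a+c)) by more than 5%")
  structure(
    list(k_N = k_N, a = a, b = b, a_plus_c = a_plus_c,
         alpha0 = alpha0, beta0 = beta0, gamma = gamma,
         sd = sd, cell_line = cell_line),
    class = "cell_params"
  )
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("IMK cell parameters: %s\n", x$cell_line))
  flds <- c("k_N", "a", "b", "a_plus_c", "alpha0", "beta0", "gamma")
  units <- c("Gy^-1", "h^-1", "h^-1", "h^-1", "Gy^-1", "Gy^-2", "Gy")
  for (i in seq_along(flds)) {
    f <- flds[i]
    sd <- x$sd[[f]]
    cat(sprintf("  %-9s %.4g%s %s\n", f, x[[f]],
                if (!is.null(sd)) sprintf(" +/- %.3g", sd) else "", units[i]))
  }
  invisible(x)
}

#' Packaged parameter sets for WI-38 fibroblasts and human lens epithelial cells
#'
#' Reads the parameter table shipped with the package (fitted values with
#' standard deviations for both cell lines under 150 kVp X-rays).
#'
#' @param line `"WI-38"`, `"HLEC"`, or `NULL` for a named list of both.
#' @param derive_rates if `TRUE`, `a` and `b` are re-derived from
#'   `(alpha0, beta0, a_plus_c, k_N)` instead of using the table's rounded
#'   values, giving an exactly self-consistent set.
#' @export
imk_cell_lines <- function(line = NULL, derive_rates = FALSE) {
  path <- system.file("extdata", "cell_params_table.json", package = "imkfit")
  tab <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  build <- function(e) {
    cell_params(
      k_N = e$k_N, a_plus_c = e$a_plus_c, alpha0 = e$alpha0, beta0 = e$beta0,
      gamma = e$gamma,
      a = if (derive_rates) NULL else e$a,
      b = if (derive_rates) NULL else e$b,
      sd = e$sd, cell_line = e$cell_line
    )
  }
  all <- lapply(tab, build)
  names(all) <- vapply(all, function(p) p$cell_line, character(1))
  if (is.null(line)) return(all)
  if (!line %in% names(all))
    stop("unknown cell line '", line, "'; available: ", paste(names(all), collapse = ", "))
  all[[line]]
}

# 1 keV/um per (g/cm^3 * um^2) expressed in Gy
.kev_per_um3_to_gy <- 1.602176634e-1

#' Single-event dose factor from microdosimetric quantities
#'
#' `gamma = y_D / (rho * pi * r_d^2)`: the dose-mean specific energy per event
#' in a spherical domain, which couples the intra-track (single-event) pair
#' term into the survival model.
#'
#' @param y_D dose-mean lineal energy, keV/um.
#' @param rho domain density, g/cm^3 (default 1, liquid water).
#' @param r_d domain radius, um (default 0.5).
#' @return gamma in Gy.
#' @examples
#' gamma_from_microdosimetry(4.677)  # ~0.954 Gy, 150 kVp X-rays
#' @export
gamma_from_microdosimetry <- function(y_D, rho = 1.0, r_d = 0.5) {
  if (any(c(y_D, rho, r_d) <= 0)) stop("y_D, rho and r_d must be positive")
  y_D / (rho * pi * r_d^2) * .kev_per_um3_to_gy
}

#' Survival coefficients from microscopic lesion rates
#'
#' `alpha0 = a k_N / (a + c)`, `beta0 = b k_N^2 / (2 (a + c))`. Evaluated
#' exactly; the frequently quoted approximation `(a + c) ~ c` is never used.
#'
#' @param k_N PLL yield per nucleus per Gy.
#' @param a first-order conversion rate, per hour.
#' @param b second-order (pairwise) conversion rate, per hour.
#' @param a_plus_c total PLL removal rate, per hour.
#' @return Named numeric vector `c(alpha0 =, beta0 =)`.
#' @export
alpha0_beta0_from_micro <- function(k_N, a, b, a_plus_c) {
  if (any(c(k_N, a_plus_c) <= 0) || a < 0 || b < 0)
    stop("rates must be non-negative and k_N, a_plus_c positive")
  c(alpha0 = a * k_N / a_plus_c, beta0 = b * k_N^2 / (2 * a_plus_c))
}

#' Microscopic lesion rates from survival coefficients
#'
#' Inverts [alpha0_beta0_from_micro()]: `a = alpha0 (a + c) / k_N`,
#' `b = 2 beta0 (a + c) / k_N^2`. Standard deviations, when given, are
#' propagated to first order (delta method) assuming independent inputs.
#'
#' @param k_N PLL yield per nucleus per Gy.
#' @param alpha0 linear survival coefficient, per Gy.
#' @param beta0 quadratic survival coefficient, per Gy^2.
#' @param a_plus_c total PLL removal rate, per hour.
#' @param sd optional named list/vector of standard deviations for any of
#'   `k_N`, `alpha0`, `beta0`, `a_plus_c` (missing entries are taken as 0).
#' @return List with elements `a`, `b` and `sd` (named vector `a`, `b`).
#' @export
micro_from_alpha0_beta0 <- function(k_N, alpha0, beta0, a_plus_c, sd = list()) {
  if (any(c(k_N, alpha0, beta0, a_plus_c) <= 0))
    stop("all inputs must be positive")
  g <- function(f) if (is.null(sd[[f]])) 0 else sd[[f]]
  a <- alpha0 * a_plus_c / k_N
  b <- 2 * beta0 * a_plus_c / k_N^2
  sd_a <- sqrt((a_plus_c / k_N * g("alpha0"))^2 +
               (alpha0 / k_N * g("a_plus_c"))^2 +
               (alpha0 * a_plus_c / k_N^2 * g("k_N"))^2)
  sd_b <- sqrt((2 * a_plus_c / k_N^2 * g("beta0"))^2 +
               (2 * beta0 / k_N^2 * g("a_plus_c"))^2 +
               (4 * beta0 * a_plus_c / k_N^3 * g("k_N"))^2)
  list(a = a, b = b, sd = c(a = sd_a, b = sd_b))
}
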