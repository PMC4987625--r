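#' Competition-ELISA series
#'
#' One replicate of a solution-phase competition ELISA: a fixed antibody
#' concentration is pre-equilibrated with a dilution series of soluble
#' antigen, and residual free antibody is read out on antigen-coated
#' wells, where absorbance is proportional to free antibody.
#'
#' @param antigen_id Antigen identifier.
#' @param a0 Soluble antigen concentrations, nM.
#' @param absorbance Absorbance at each `a0`.
#' @param A0 Absorbance with no competing antigen.
#' @param coating Coating concentration of the replicate plate, nM
#'   (replicate label; does not enter the estimator).
#' @param antibody_conc Fixed antibody concentration, nM (default 0.7).
#' @return Object of class `elisa_series`.
#' @export
elisa_series <- function(antigen_id, a0, absorbance, A0,
                         coating = NA_real_, antibody_conc = 0.7) {
  stopifnot(length(a0) == length(absorbance), length(A0) == 1L)
  if (any(a0 <= 0)) stop("antigen concentrations a0 must be positive")
  if (A0 <= 0) stop("A0 must be positive")
  if (any(absorbance < 0)) stop("absorbances must be non-negative")
  structure(list(antigen_id = as.character(antigen_id),
                 a0 = as.numeric(a0), absorbance = as.numeric(absorbance),
                 A0 = as.numeric(A0), coating = coating,
                 antibody_conc = antibody_conc),
            class = "elisa_series")
}

#' Solution-phase K_D by the Friguet plot
#'
#' Linearises the competition isotherm under the antigen-excess
#' approximation (free antigen ~ total antigen `a0`): plotting
#' `y = A0 / (A0 - A)` against `x = 1 / a0` gives a straight line with
#' intercept 1 and slope K_D, fitted here by ordinary least squares.
#' Points with `A >= A0` carry no inhibition signal, are undefined on
#' the y axis, and are dropped with a warning; a series in which every
#' point is non-inhibiting returns a no-binding result.
#'
#' @param series An [elisa_series()].
#' @return Object of class `friguet_fit`: list with `kd` (nM, `NA` when
#'   `no_binding`), `intercept`, `no_binding`, `n_points`,
#'   `dropped_points`, `antigen_id`, `coating`.
#' @export
friguet_kd <- function(series) {
  stopifnot(inherits(series, "elisa_series"))
  inh <- series$absorbance < series$A0
  if (!any(inh)) {
    return(structure(list(kd = NA_real_, intercept = NA_real_,
                          no_binding = TRUE, n_points = 0L,
                          dropped_points = sum(!inh),
                          antigen_id = series$antigen_id,
                          coating = series$coating),
                     class = "friguet_fit"))
  }
  if (sum(!inh) > 0L)
    warning(sum(!inh), " non-inhibiting point(s) (A >= A0) dropped ",
            "from the regression")
  if (sum(inh) < 2L)
    stop("fewer than 2 informative points: cannot regress")
  if (any(series$a0[inh] < 10 * series$antibody_conc))
    warning("some antigen concentrations are below 10x the antibody ",
            "concentration; the antigen-excess approximation may bias K_D")
  y <- series$A0 / (series$A0 - series$absorbance[inh])
  x <- 1 / series$a0[inh]
  fit <- lm(y ~ x)
  b <- unname(coef(fit)[1]); m <- unname(coef(fit)[2])
  if (abs(b - 1) > 0.2)
    warning(sprintf(
      "Friguet intercept %.3f deviates from 1 by more than 0.2; ",
      b), "the linear model may not describe these data")
  structure(list(kd = m, intercept = b, no_binding = FALSE,
                 n_points = sum(inh), dropped_points = sum(!inh),
                 antigen_id = series$antigen_id,
                 coating = series$coating),
            class = "friguet_fit")
}

#' @export
print.friguet_fit <- function(x, ...) {
  if (x$no_binding) {
    cat("<friguet_fit> ", x$antigen_id, ": no binding detected\n",
        sep = "")
  } else {
    cat(sprintf("<friguet_fit> %s: K_D = %.4g nM (intercept %.3f, %d points)\n",
                x$antigen_id, x$kd, x$intercept, x$n_points))
  }
  invisible(x)
}

#' Aggregate replicate K_D estimates
#'
#' Mean and sample standard deviation of the per-replicate (per coating
#' concentration) K_D values, with an optional fold change relative to a
#' reference antigen's estimate.  The estimate is flagged no-binding
#' when every replicate is.
#'
#' @param fits List of [friguet_kd()] fits (or of [elisa_series()],
#'   which are fitted first) for one antigen.
#' @param reference Optional `kd_estimate` of the reference antigen.
#' @return Object of class `kd_estimate`: `antigen_id`, `kd_values`,
#'   `kd_mean`, `kd_sd` (0 for a single replicate),
#'   `fold_change_vs_reference`, `no_binding`.
#' @export
aggregate_kd <- function(fits, reference = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  fits <- lapply(fits, function(f)
    if (inherits(f, "elisa_series")) friguet_kd(f) else f)
  stopifnot(all(vapply(fits, inherits, logical(1), "friguet_fit")))
  ids <- unique(vapply(fits, `[[`, character(1), "antigen_id"))
  if (length(ids) != 1L)
    stop("replicates mix antigen ids: ", paste(ids, collapse = ", "))
  kd <- vapply(fits, `[[`, numeric(1), "kd")
  nb <- vapply(fits, `[[`, logical(1), "no_binding")
  if (all(nb)) {
    est <- list(antigen_id = ids, kd_values = kd, kd_mean = NA_real_,
                kd_sd = NA_real_, fold_change_vs_reference = NA_real_,
                no_binding = TRUE)
    return(structure(est, class = "kd_estimate"))
  }
  kd <- kd[!nb]
  if (any(nb))
    warning(sum(nb), " no-binding replicate(s) excluded from the mean")
  est <- list(antigen_id = ids, kd_values = kd, kd_mean = mean(kd),
              kd_sd = if (length(kd) > 1L) sd(kd) else 0,
              fold_change_vs_reference = NA_real_, no_binding = FALSE)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "kd_estimate"))
    if (!reference$no_binding)
      est$fold_change_vs_reference <- est$kd_mean / reference$kd_mean
  }
  structure(est, class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (x$no_binding) {
    cat("<kd_estimate> ", x$antigen_id, ": no interaction detected\n",
        sep = "")
  } else {
    cat(sprintf("<kd_estimate> %s: K_D = %.3g +/- %.2g nM (n = %d)",
                x$antigen_id, x$kd_mean, x$kd_sd, length(x$kd_values)))
    if (!is.na(x$fold_change_vs_reference))
      cat(sprintf("; fold change vs reference = %.2f",
                  x$fold_change_vs_reference))
    cat("\n")
  }
  invisible(x)
}

#' Simulate a competition-ELISA series
#'
#' Generates absorbances from the equilibrium binding isotherm for a
#' known K_D, either under the antigen-excess approximation
#' (`A = A0 * KD / (KD + a0)`, the model the Friguet plot linearises)
#' or from the exact bimolecular equilibrium (solving the quadratic for
#' the antigen-antibody complex), plus optional Gaussian absorbance
#' noise.
#'
#' @param kd True dissociation constant, nM.
#' @param a0 Antigen concentration grid, nM (default: seven doubling
#'   steps from 7 to 480 nM).
#' @param antibody_conc Antibody concentration, nM.
#' @param A0 Absorbance without competitor.
#' @param noise_sd Gaussian absorbance noise standard deviation.
#' @param exact Use the exact equilibrium instead of the antigen-excess
#'   approximation.
#' @param antigen_id,coating Labels for the resulting series.
#' @return An [elisa_series()].
#' @export
simulate_elisa_series <- function(kd, a0 = c(7, 15, 30, 60, 120, 240, 480),
                                  antibody_conc = 0.7, A0 = 1,
                                  noise_sd = 0, exact = FALSE,
                                  antigen_id = "antigen",
                                  coating = NA_real_) {
  stopifnot(kd > 0, all(a0 > 0))
  if (exact) {
    i0 <- antibody_conc
    s <- a0 + i0 + kd
    cplx <- (s - sqrt(s^2 - 4 * a0 * i0)) / 2
    free_frac <- (i0 - cplx) / i0
  } else {
    free_frac <- kd / (kd + a0)
  }
  A <- A0 * free_frac
  if (noise_sd > 0) A <- pmax(0, A + stats::rnorm(length(A), 0, noise_sd))
  elisa_series(antigen_id, a0, A, A0 = A0, coating = coating,
               antibody_conc = antibody_conc)
}

#' Read competition-ELISA data from CSV
#'
#' Expected columns: `antigen_id`, `coating_nM`, `a0_nM`, `absorbance`.
#' Rows with `a0_nM == 0` carry the no-competitor absorbance `A0` for
#' their (antigen, coating) replicate.
#'
#' @param path CSV path.
#' @param antibody_conc Antibody concentration, nM.
#' @return Named list (by antigen) of lists of [elisa_series()], one per
#'   coating replicate.
#' @export
read_elisa_csv <- function(path, antibody_conc = 0.7) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("antigen_id", "coating_nM", "a0_nM", "absorbance")
  if (!all(need %in% names(d)))
    stop("ELISA CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (ag in unique(d$antigen_id)) {
    da <- d[d$antigen_id == ag, , drop = FALSE]
    reps <- list()
    for (co in unique(da$coating_nM)) {
      dc <- da[da$coating_nM == co, , drop = FALSE]
      a0row <- dc$a0_nM == 0
      if (sum(a0row) != 1L)
        stop("antigen ", ag, ", coating ", co,
             ": need exactly one A0 row (a0_nM == 0)")
      reps[[length(reps) + 1L]] <- elisa_series(
        ag, dc$a0_nM[!a0row], dc$absorbance[!a0row],
        A0 = dc$absorbance[a0row], coating = co,
        antibody_conc = antibody_conc)
    }
    out[[ag]] <- reps
  }
  out
}
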