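# Linear combinations of collective variables: screening and simulated
# annealing over coefficients under an L1 normalisation constraint.

#' Make sample CVs dimensionless
#'
#' Divides each CV by its unit quantum -- 1 Angstrom for distance CVs,
#' 1 nm^-3 for density CVs -- so coefficients of linear combinations are
#' comparable; dimensionless CVs pass unchanged. Numerically this is the
#' identity; the operation validates the unit annotation and marks the
#' samples dimensionless.
#'
#' @param samples a `ppa_samples` data.frame with one or more CV columns.
#' @param units named character vector, one of `"angstrom"`/`"A"`,
#'   `"nm^-3"`/`"nm-3"`, `"unitless"`/`"1"` per CV column.
#' @return The samples with a `units` attribute of `"unitless"` entries.
#' @export
nondimensionalize <- function(samples, units) {
  known <- c(angstrom = 1, A = 1, `nm^-3` = 1, `nm-3` = 1, unitless = 1, `1` = 1)
  cvs <- setdiff(names(samples), c("path_id", "weight", "label"))
  for (cv in cvs) {
    u <- if (cv %in% names(units)) units[[cv]] else NULL
    if (is.null(u))
      ppa_error(sprintf("no unit given for CV '%s'", cv), "ppa_value_error")
    if (!u %in% names(known))
      ppa_error(sprintf("unknown unit '%s' for CV '%s'", u, cv),
                "ppa_value_error")
    samples[[cv]] <- samples[[cv]] / known[[u]]
  }
  attr(samples, "units") <- stats::setNames(rep("unitless", length(cvs)), cvs)
  samples
}

#' Normalise coefficients to unit L1 norm
#'
#' @param coefs numeric vector, not all zero.
#' @return `coefs / sum(abs(coefs))`, satisfying
#'   \eqn{\sum_i |c_i| = 1}.
#' @export
normalize_l1 <- function(coefs) {
  s <- sum(abs(coefs))
  if (s == 0) ppa_error("all coefficients are zero", "ppa_value_error")
  coefs / s
}

#' Linear combination of collective variables
#'
#' \eqn{\Psi = \alpha\,CV_i + \beta\,CV_j + \gamma\,CV_k} with 1 to 3 terms,
#' constrained by \eqn{|\alpha| + |\beta| + |\gamma| = 1} (an overall scaling
#' has no effect on the predictive capacity).
#'
#' @param cv_names names of the combined CVs.
#' @param coefficients numeric coefficients, L1-normalised on construction.
#' @return An object of class `ppa_combo` with element `terms`, a named
#'   coefficient vector.
#' @export
linear_combo <- function(cv_names, coefficients) {
  if (length(cv_names) != length(coefficients))
    ppa_error("one coefficient per CV required", "ppa_value_error")
  if (length(cv_names) < 1L || length(cv_names) > 3L)
    ppa_error("a combination has 1 to 3 terms", "ppa_value_error")
  structure(list(terms = stats::setNames(normalize_l1(coefficients), cv_names)),
            class = "ppa_combo")
}

#' @export
print.ppa_combo <- function(x, ...) {
  co <- x$terms
  cat("<ppa_combo> Psi =",
      paste(sprintf("%+.3f %s", co, names(co)), collapse = " "), "\n")
  invisible(x)
}

#' Project samples onto a linear combination
#'
#' Replaces the CV columns by the single projected CV
#' \eqn{\Psi = \sum_i c_i\,CV_i}; weights and labels carry through.
#'
#' @param samples a `ppa_samples` data.frame.
#' @param combo a [linear_combo()].
#' @return A `ppa_samples` data.frame with single CV column `psi`.
#' @export
combo_project <- function(samples, combo) {
  stopifnot(inherits(combo, "ppa_combo"))
  miss <- setdiff(names(combo$terms), names(samples))
  if (length(miss))
    ppa_error(sprintf("missing CV '%s' in samples", miss[1L]),
              "ppa_value_error")
  M <- as.matrix(samples[names(combo$terms)])
  out <- data.frame(path_id = samples$path_id,
                    psi = as.vector(M %*% combo$terms),
                    weight = samples$weight, label = samples$label)
  structure(out, lam_c = attr(samples, "lam_c"), lam_r = attr(samples, "lam_r"),
            class = c("ppa_samples", "data.frame"))
}

#' Rank single CVs by predictive capacity
#'
#' Computes [capacity_from_samples()] for each CV separately and ranks them
#' in decreasing capacity, ties broken lexicographically by name.
#'
#' @param samples a `ppa_samples` data.frame with the candidate CV columns.
#' @param cv_names candidates; defaults to every CV column.
#' @param settings a [sg_settings()] object.
#' @return A data.frame with columns `cv`, `capacity`, `p_bar`, `overlap`.
#' @export
screen_singles <- function(samples, cv_names = NULL, settings = sg_settings()) {
  cvs <- setdiff(names(samples), c("path_id", "weight", "label"))
  if (is.null(cv_names)) cv_names <- cvs
  if (!length(cv_names)) ppa_error("no candidate CVs", "ppa_value_error")
  miss <- setdiff(cv_names, cvs)
  if (length(miss))
    ppa_error(sprintf("unknown CV '%s'", miss[1L]), "ppa_value_error")
  res <- lapply(cv_names, function(cv)
    capacity_from_samples(samples, settings, cv = cv))
  out <- data.frame(cv = cv_names,
                    capacity = vapply(res, `[[`, 0, "capacity"),
                    p_bar = vapply(res, `[[`, 0, "p_bar"),
                    overlap = vapply(res, `[[`, 0, "overlap"))
  out <- out[order(-out$capacity, out$cv), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulated-annealing settings for the combination search
#'
#' The screening stage uses generalized simulated annealing at an initial
#' temperature of 26,150 with 200 optimisation iterations for two-CV
#' combinations and 1000 for three; promising candidates are refined by a
#' local search. The temperature is an opaque scale of the underlying
#' annealer.
#'
#' @param initial_temperature annealing start temperature (default 26150).
#' @param max_iterations iteration budget; defaults to 200 (2 CVs) or 1000
#'   (3 CVs) when `NULL`.
#' @param seed master seed; restart seeds derive from it deterministically.
#' @param local_search run a Nelder-Mead refinement of the best candidate.
#' @param restarts annealing restarts per CV subset (default 3).
#' @param top_k subsets are enumerated from the `top_k` best-screened CVs.
#' @return An object of class `ppa_anneal_settings`.
#' @export
anneal_settings <- function(initial_temperature = 26150,
                            max_iterations = NULL, seed = 1L,
                            local_search = TRUE, restarts = 3L,
                            top_k = 10L) {
  if (initial_temperature <= 0)
    ppa_error("initial_temperature must be positive", "ppa_value_error")
  if (!is.null(max_iterations) && max_iterations < 1)
    ppa_error("max_iterations must be positive", "ppa_value_error")
  structure(list(initial_temperature = initial_temperature,
                 max_iterations = max_iterations, seed = as.integer(seed),
                 local_search = isTRUE(local_search),
                 restarts = as.integer(restarts), top_k = as.integer(top_k)),
            class = "ppa_anneal_settings")
}

#' Optimise a linear CV combination by simulated annealing
#'
#' Enumerates all `n_terms`-subsets of the candidate CVs (pre-screened to the
#' `top_k` individually most predictive when there are more), and for each
#' subset anneals the coefficients in \eqn{[-1, 1]^n} -- re-normalised to
#' \eqn{\sum|c_i| = 1} before every evaluation -- to minimise the overlap
#' integral (equivalent to maximising the predictive capacity, since
#' \eqn{\bar p} does not depend on the CV). The best subset is refined by a
#' local Nelder-Mead search. Deterministic for a fixed seed. The leading
#' (largest-magnitude) coefficient of the reported combination is made
#' positive; `normalized_coefficients` additionally rescales by the largest
#' absolute coefficient, the conventional reporting form.
#'
#' @param samples a `ppa_samples` data.frame holding the candidate CVs.
#' @param candidate_cvs candidate CV names.
#' @param n_terms 2 or 3.
#' @param settings an [anneal_settings()] object.
#' @param sg a [sg_settings()] object for the capacity evaluations.
#' @return A list of class `ppa_anneal_result`: `combo` ([linear_combo()]),
#'   `result` (`ppa_capacity`), `normalized_coefficients`, `screened`.
#' @export
anneal_combo <- function(samples, candidate_cvs, n_terms = 2L,
                         settings = anneal_settings(), sg = sg_settings()) {
  if (!n_terms %in% c(2L, 3L))
    ppa_error("n_terms must be 2 or 3", "ppa_value_error")
  if (length(candidate_cvs) < n_terms)
    ppa_error(sprintf("need at least %d candidate CVs, have %d", n_terms,
                      length(candidate_cvs)), "ppa_value_error")
  iters <- settings$max_iterations %||% if (n_terms == 2L) 200L else 1000L

  screened <- screen_singles(samples, candidate_cvs, sg)
  if (length(candidate_cvs) > settings$top_k)
    candidate_cvs <- screened$cv[seq_len(settings$top_k)]
  subsets <- utils::combn(sort(candidate_cvs), n_terms, simplify = FALSE)

  w <- samples$weight
  lab <- samples$label
  loss_for <- function(cvs) {
    M <- as.matrix(samples[cvs])
    function(coef) {
      coef <- pmin(pmax(coef, -1), 1)
      if (sum(abs(coef)) < 1e-12) return(1)
      psi <- as.vector(M %*% normalize_l1(coef))
      d <- tryCatch(density_from_vectors(psi, w, lab, sg),
                    ppa_error = function(e) NULL)
      if (is.null(d)) return(1)
      overlap_integral(d)
    }
  }

  best <- list(value = Inf)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (si in seq_along(subsets)) {
    fn <- loss_for(subsets[[si]])
    for (r in seq_len(settings$restarts)) {
      set.seed((settings$seed * 7919L + si * 101L + r) %% .Machine$integer.max)
      fit <- stats::optim(stats::runif(n_terms, -1, 1), fn, method = "SANN",
                          control = list(temp = settings$initial_temperature,
                                         maxit = iters))
      if (fit$value < best$value)
        best <- list(value = fit$value, par = fit$par, cvs = subsets[[si]],
                     fn = fn)
    }
  }

  if (settings$local_search) {
    fit <- stats::optim(best$par, best$fn, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10))
    if (fit$value <= best$value) best[c("value", "par")] <- fit[c("value", "par")]
  }

  coef <- normalize_l1(pmin(pmax(best$par, -1), 1))
  lead <- which.max(abs(coef))
  coef <- coef * sign(coef[lead])
  combo <- linear_combo(best$cvs, coef)
  projected <- combo_project(samples, combo)
  result <- capacity_from_samples(projected, sg)
  structure(list(combo = combo, result = result,
                 normalized_coefficients =
                   stats::setNames(coef / max(abs(coef)), best$cvs),
                 screened = screened),
            class = "ppa_anneal_result")
}

#' @export
print.ppa_anneal_result <- function(x, ...) {
  print(x$combo)
  cat(sprintf("  capacity %.4f (p_bar %.4f, overlap %.4g)\n",
              x$result$capacity, x$result$p_bar, x$result$overlap))
  invisible(x)
}
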