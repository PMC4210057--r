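#' Enumerate candidate pollutant subsets
#'
#' All non-empty subsets of the pollutant names, ordered by size then
#' lexicographically; with the five study pollutants this yields the 31
#' candidate models of the subset sweep.
#'
#' @param pollutants character vector of unique pollutant names.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(pollutants) {
  pollutants <- as.character(pollutants)
  if (!length(pollutants)) stop("pollutant list must be non-empty")
  if (anyDuplicated(pollutants)) stop("duplicate pollutant names")
  out <- list()
  for (k in seq_along(pollutants)) {
    combos <- utils::combn(sort(pollutants), k, simplify = FALSE)
    ord <- order(vapply(combos, paste, "", collapse = "\r"))
    out <- c(out, combos[ord])
  }
  out
}

#' Fit every candidate pollutant subset
#'
#' Fits the STAR model once per subset (shared smooth/spatial settings taken
#' from `base_spec`), recording AIC and per-pollutant estimates. Fits that
#' fail to converge are kept with `converged = FALSE` and excluded by
#' [screen_and_rank()].
#'
#' @param panel,covariates,calendar,graph as in [build_design()].
#' @param base_spec a [model_spec] whose non-pollutant settings are reused.
#' @param subsets list of pollutant subsets (default: all non-empty subsets
#'   of the five study pollutants present in `covariates`).
#' @param control passed to [fit_star()].
#' @param verbose print one line per candidate.
#' @return list of candidate records (class `candidate_result`): `subset`,
#'   `aic`, `estimates` (coef, se per pollutant), `converged`, `message`.
#' @export
fit_candidates <- function(panel, covariates, calendar, graph,
                           base_spec = model_spec(),
                           subsets = NULL, control = list(), verbose = FALSE) {
  if (is.null(subsets)) {
    pool <- intersect(c("CO", "NOx", "O3", "PM10", "SO2"), names(covariates))
    subsets <- enumerate_subsets(pool)
  }
  lapply(subsets, function(ss) {
    spec <- base_spec
    spec$pollutants <- ss
    rec <- list(subset = ss, aic = NA_real_, estimates = NULL,
                converged = FALSE, message = "")
    fit <- tryCatch({
      d <- build_design(panel, covariates, calendar, graph, spec)
      fit_star(d, control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      rec$message <- conditionMessage(fit)
    } else {
      rec$aic <- fit$aic
      rec$estimates <- data.frame(pollutant = ss,
                                  coef = unname(fit$coefficients[ss]),
                                  se = unname(fit$se[ss]))
      rec$converged <- TRUE
    }
    if (verbose)
      message(sprintf("[%s] AIC %.2f %s", paste(ss, collapse = "+"),
                      rec$aic, if (rec$converged) "" else "(failed)"))
    class(rec) <- "candidate_result"
    rec
  })
}

#' Screen candidates and rank the eligible ones by AIC
#'
#' A candidate is eligible only if every pollutant coefficient is
#' significantly positive (its Gaussian `1 - alpha` confidence interval lies
#' above zero); models with any non-significant or significantly negative
#' pollutant are excluded, as are non-converged fits. The selected model is
#' the eligible candidate with smallest AIC; ties break toward the smaller
#' subset, then lexicographically.
#'
#' @param candidates list of candidate records from [fit_candidates()].
#' @param alpha significance level (default 0.05, i.e. 95% intervals).
#' @return list with `table` (one row per candidate: subset, aic, status,
#'   reason), `eligible` (ranked data frame), and `selected` (character
#'   vector of pollutant names, or `NULL` with a message if no candidate
#'   survives screening).
#' @export
screen_and_rank <- function(candidates, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  rows <- lapply(candidates, function(rec) {
    label <- paste(rec$subset, collapse = "+")
    if (!rec$converged)
      return(data.frame(subset = label, size = length(rec$subset),
                        aic = NA_real_, status = "excluded",
                        reason = paste("non-converged:", rec$message)))
    lo <- rec$estimates$coef - z * rec$estimates$se
    ok <- all(lo > 0 & rec$estimates$coef > 0)
    data.frame(subset = label, size = length(rec$subset), aic = rec$aic,
               status = if (ok) "eligible" else "excluded",
               reason = if (ok) "" else "non-significant or negative pollutant estimate")
  })
  tab <- do.call(rbind, rows)
  elig <- tab[tab$status == "eligible", , drop = FALSE]
  if (!nrow(elig)) {
    return(list(table = tab, eligible = elig, selected = NULL,
                message = "no candidate has all pollutant effects significantly positive"))
  }
  elig <- elig[order(elig$aic, elig$size, elig$subset), , drop = FALSE]
  selected <- strsplit(elig$subset[1], "+", fixed = TRUE)[[1]]
  list(table = tab, eligible = elig, selected = selected, message = "")
}

#' One-shot pollutant selection
#'
#' Convenience wrapper: [fit_candidates()] over all subsets (or a staged
#' build-up mirroring the narrated selection procedure: single-pollutant
#' screen first, then multi-pollutant models over the survivors), followed
#' by [screen_and_rank()].
#'
#' @inheritParams fit_candidates
#' @param strategy `"all_subsets"` (default, the full sweep) or `"staged"`.
#' @param alpha significance level for screening.
#' @return as [screen_and_rank()], plus `candidates`.
#' @export
select_pollutants <- function(panel, covariates, calendar, graph,
                              base_spec = model_spec(),
                              strategy = c("all_subsets", "staged"),
                              alpha = 0.05, control = list(), verbose = FALSE) {
  strategy <- match.arg(strategy)
  pool <- intersect(c("CO", "NOx", "O3", "PM10", "SO2"), names(covariates))
  if (strategy == "all_subsets") {
    cands <- fit_candidates(panel, covariates, calendar, graph, base_spec,
                            enumerate_subsets(pool), control, verbose)
  } else {
    singles <- fit_candidates(panel, covariates, calendar, graph, base_spec,
                              as.list(pool), control, verbose)
    keep <- screen_and_rank(singles, alpha)
    survivors <- sort(unique(unlist(lapply(
      singles[vapply(seq_along(singles), function(i)
        keep$table$status[i] == "eligible", TRUE)], `[[`, "subset"))))
    extra <- if (length(survivors) >= 2)
      Filter(function(s) length(s) >= 2, enumerate_subsets(survivors))
    else list()
    cands <- c(singles, if (length(extra))
      fit_candidates(panel, covariates, calendar, graph, base_spec,
                     extra, control, verbose))
  }
  out <- screen_and_rank(cands, alpha)
  out$candidates <- cands
  out
}
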