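#' Model specification for the STAR fit
#'
#' Describes which terms enter the structured additive predictor
#' `log mu_dt = X beta + Z gamma + f(time) + f(temp) + f_spat(d) + log(POP_d)`.
#'
#' @param pollutants character subset of the pollutant columns to include as
#'   linear terms (possibly empty for the baseline model).
#' @param n_basis_time,n_basis_temp B-spline basis dimensions for the
#'   calendar-time and temperature smooths (defaults 20 and 10, common
#'   P-spline practice; the basis dimension is an upper bound on roughness,
#'   the RW2 penalty does the actual smoothing).
#' @param degree spline degree (default cubic).
#' @param dow_reference reference weekday (default `"Sun"`).
#' @param use_time,use_temp,use_spatial logical switches for the penalized
#'   terms (all `TRUE` by default; turning all off yields a plain GLM).
#' @param pollutant_lag non-negative integer day lag applied to pollutant
#'   series (default 0, same-day exposure).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(pollutants = character(0), n_basis_time = 20L,
                       n_basis_temp = 10L, degree = 3L, dow_reference = "Sun",
                       use_time = TRUE, use_temp = TRUE, use_spatial = TRUE,
                       pollutant_lag = 0L) {
  pollutants <- as.character(pollutants)
  if (anyDuplicated(pollutants)) stop("duplicate pollutant names")
  structure(list(pollutants = pollutants, n_basis_time = as.integer(n_basis_time),
                 n_basis_temp = as.integer(n_basis_temp), degree = as.integer(degree),
                 dow_reference = dow_reference, use_time = isTRUE(use_time),
                 use_temp = isTRUE(use_temp), use_spatial = isTRUE(use_spatial),
                 pollutant_lag = as.integer(pollutant_lag)),
            class = "model_spec")
}

#' Assemble the STAR design from panel, calendar, covariates and graph
#'
#' Validates the panel (one row per district x date, integer non-negative
#' counts, positive populations, no internal date gaps unless allowed),
#' joins the single-station daily covariates, and builds the design blocks:
#' fixed effects (intercept, 6 DOW dummies, ADS and post-ADS indicators),
#' linear pollutant columns in raw units, sum-to-zero-constrained P-spline
#' blocks for calendar time and temperature, a sum-to-zero-constrained CAR
#' spatial block, and the `log(population)` offset.
#'
#' @param panel data frame with columns `district`, `date`, `count`,
#'   `population`.
#' @param covariates data frame with column `date`, pollutant columns, and
#'   `temperature`.
#' @param calendar an [exposure_calendar][label_periods] covering the panel dates.
#' @param graph a [district_graph] covering the panel districts.
#' @param spec a [model_spec].
#' @param allow_gaps tolerate missing dates inside the panel range.
#' @return an object of class `star_design`: list with the full design
#'   matrix `X`, response `y`, `offset`, a `blocks` list (name, column
#'   indices, penalty matrix and rank for penalized blocks), and `meta`
#'   carrying what reporting needs (spline blocks, spatial transform,
#'   district order, dates, spec).
#' @export
build_design <- function(panel, covariates, calendar, graph, spec,
                         allow_gaps = FALSE) {
  stopifnot(inherits(calendar, "exposure_calendar"),
            inherits(graph, "district_graph"), inherits(spec, "model_spec"))
  need <- c("district", "date", "count", "population")
  if (!all(need %in% names(panel)))
    stop(sprintf("panel must have columns %s", paste(need, collapse = ", ")))
  panel$date <- as.Date(panel$date)
  panel$district <- as.character(panel$district)
  if (any(panel$count < 0) || any(panel$count != round(panel$count)))
    stop("counts must be non-negative integers")
  if (any(panel$population <= 0)) stop("populations must be positive")

  missing_d <- setdiff(unique(panel$district), graph$ids)
  if (length(missing_d))
    stop(sprintf("district(s) in panel missing from graph: %s",
                 paste(missing_d, collapse = ", ")))
  districts <- graph$ids[graph$ids %in% unique(panel$district)]

  dates <- sort(unique(panel$date))
  full_seq <- seq(min(dates), max(dates), by = "day")
  if (!allow_gaps && length(dates) != length(full_seq))
    stop(sprintf("panel has %d missing date(s) inside its range; set allow_gaps = TRUE to accept",
                 length(full_seq) - length(dates)))
  if (nrow(panel) != length(dates) * length(districts) ||
      anyDuplicated(panel[c("district", "date")]))
    stop("panel must contain exactly one row per district x date")
  if (!all(dates %in% calendar$date)) stop("calendar does not cover all panel dates")

  covariates$date <- as.Date(covariates$date)
  if (spec$pollutant_lag > 0L)
    covariates <- .lag_covariates(covariates, spec$pollutant_lag, spec$pollutants)
  if (!all(dates %in% covariates$date)) stop("covariates do not cover all panel dates")
  miss_p <- setdiff(spec$pollutants, names(covariates))
  if (length(miss_p))
    stop(sprintf("pollutant(s) not in covariate table: %s", paste(miss_p, collapse = ", ")))
  if (!"temperature" %in% names(covariates) && spec$use_temp)
    stop("covariates must contain a 'temperature' column")

  # canonical row order: date-major, district within date
  panel <- panel[order(panel$date, match(panel$district, districts)), ]
  day_ix <- match(panel$date, dates)
  dist_ix <- match(panel$district, districts)

  cal <- calendar[match(dates, calendar$date), ]
  class(cal) <- class(calendar)
  Xdow_day <- dow_design(cal, reference = spec$dow_reference)
  Xfix_day <- cbind(`(Intercept)` = 1, Xdow_day,
                    I_ADS = as.numeric(cal$period == "ADS"),
                    I_POST_ADS = as.numeric(cal$period == "POST_ADS"))
  X <- Xfix_day[day_ix, , drop = FALSE]
  blocks <- list(list(name = "fixed", idx = seq_len(ncol(X)), penalty = NULL))

  cov_day <- covariates[match(dates, covariates$date), , drop = FALSE]
  if (length(spec$pollutants)) {
    Z <- as.matrix(cov_day[, spec$pollutants, drop = FALSE])[day_ix, , drop = FALSE]
    if (any(!is.finite(Z))) stop("non-finite pollutant values")
    blocks[[length(blocks) + 1L]] <-
      list(name = "pollutants", idx = ncol(X) + seq_len(ncol(Z)), penalty = NULL)
    colnames(Z) <- spec$pollutants
    X <- cbind(X, Z)
  }

  meta <- list(districts = districts, dates = dates, spec = spec,
               dist_ix = dist_ix, day_ix = day_ix, calendar = cal,
               cov_day = cov_day)

  if (spec$use_time) {
    tnum <- as.numeric(dates - min(dates))
    sb <- apply_sum_to_zero(spline_block(tnum, spec$n_basis_time, spec$degree))
    Bt <- sb$B[day_ix, , drop = FALSE]
    colnames(Bt) <- paste0("f_time.", seq_len(ncol(Bt)))
    blocks[[length(blocks) + 1L]] <-
      list(name = "f_time", idx = ncol(X) + seq_len(ncol(Bt)),
           penalty = sb$K, rank = ncol(sb$K) - 1L)  # RW2 rank m-2, constraint removes one null dir
    X <- cbind(X, Bt)
    meta$time_block <- sb
  }
  if (spec$use_temp) {
    tp <- cov_day$temperature
    if (any(!is.finite(tp))) stop("non-finite temperature values")
    sb <- apply_sum_to_zero(spline_block(tp, spec$n_basis_temp, spec$degree))
    Btp <- sb$B[day_ix, , drop = FALSE]
    colnames(Btp) <- paste0("f_temp.", seq_len(ncol(Btp)))
    blocks[[length(blocks) + 1L]] <-
      list(name = "f_temp", idx = ncol(X) + seq_len(ncol(Btp)),
           penalty = sb$K, rank = ncol(sb$K) - 1L)
    X <- cbind(X, Btp)
    meta$temp_block <- sb
  }
  if (spec$use_spatial) {
    sub <- district_graph_subset(graph, districts)
    cs <- car_structure(sub)
    Zs <- nullspace_transform(rep(1, length(districts)))
    Ks <- crossprod(Zs, cs$K %*% Zs)
    Ks <- (Ks + t(Ks)) / 2
    Ms <- Zs[dist_ix, , drop = FALSE]
    colnames(Ms) <- paste0("f_spat.", seq_len(ncol(Ms)))
    blocks[[length(blocks) + 1L]] <-
      list(name = "f_spat", idx = ncol(X) + seq_len(ncol(Ms)),
           penalty = Ks, rank = length(districts) - cs$n_components)
    X <- cbind(X, Ms)
    meta$spat_Z <- Zs
    meta$car <- cs
  }

  structure(list(X = X, y = panel$count, offset = log(panel$population),
                 blocks = blocks, meta = meta),
            class = "star_design")
}

# restrict a graph to a district subset (edges within the subset)
district_graph_subset <- function(graph, ids) {
  if (setequal(ids, graph$ids) && all(ids == graph$ids)) return(graph)
  nb <- lapply(setNames(ids, ids), function(i) intersect(graph$neighbors[[i]], ids))
  nn <- vapply(nb, length, integer(1))
  structure(list(ids = ids, neighbors = nb, n_neighbors = nn,
                 isolated = ids[nn == 0L]), class = "district_graph")
}

.lag_covariates <- function(covariates, lag, pollutants) {
  covariates <- covariates[order(covariates$date), ]
  for (p in intersect(pollutants, names(covariates)))
    covariates[[p]] <- c(rep(NA_real_, lag), head(covariates[[p]], -lag))
  covariates[-seq_len(lag), , drop = FALSE]
}

default_control <- function() {
  list(inner_tol = 1e-8, inner_maxit = 100L,
       outer_tol = 1e-6, outer_maxit = 200L,
       ig_a = 0.001, ig_b = 0.001, use_ig = TRUE,
       tau2_init = 0.1, tau2_floor = 1e-10, tau2_cap = 1e8)
}

#' Penalized IRLS at fixed smoothing variances
#'
#' Maximizes the penalized Poisson log-likelihood for fixed variance
#' parameters by iteratively reweighted penalized least squares with
#' step-halving. This is the inner loop of [fit_star()]; it is exported so
#' the unpenalized special case can be compared against a standard GLM.
#'
#' @param design a [star_design][build_design].
#' @param variances named numeric vector of variances `tau^2` for the
#'   penalized blocks (`f_time`, `f_temp`, `f_spat` as present). The
#'   smoothing parameter of block j is `1 / tau2_j`.
#' @param control list of tolerances, see `adstar:::default_control()`.
#' @param beta_init optional starting coefficients.
#' @return an object of class `star_fit` (with `variances` as supplied and
#'   no outer-loop information).
#' @export
fit_pirls <- function(design, variances = NULL, control = list(),
                      beta_init = NULL) {
  ctl <- utils::modifyList(default_control(), control)
  st <- .pirls_state(design, variances, ctl)
  res <- .pirls_run(st, ctl, beta_init)
  .as_star_fit(design, res, st, outer_iter = 0L, converged_outer = NA)
}

# Precompute what PIRLS needs: penalty S at current variances, block layout.
.pirls_state <- function(design, variances, ctl) {
  stopifnot(inherits(design, "star_design"))
  pen_blocks <- Filter(function(b) !is.null(b$penalty), design$blocks)
  pen_names <- vapply(pen_blocks, `[[`, "", "name")
  if (is.null(variances))
    variances <- setNames(rep(ctl$tau2_init, length(pen_names)), pen_names)
  if (length(pen_names) && !all(pen_names %in% names(variances)))
    stop(sprintf("variances must be named; missing: %s",
                 paste(setdiff(pen_names, names(variances)), collapse = ", ")))
  if (any(variances <= 0)) stop("variances must be > 0")
  p <- ncol(design$X)
  S <- matrix(0, p, p)
  for (b in pen_blocks)
    S[b$idx, b$idx] <- b$penalty / variances[[b$name]]
  list(design = design, S = S, pen_blocks = pen_blocks,
       variances = variances[pen_names])
}

.pirls_run <- function(st, ctl, beta_init = NULL) {
  X <- st$design$X; y <- st$design$y; off <- st$design$offset
  p <- ncol(X)
  beta <- if (is.null(beta_init)) {
    b0 <- numeric(p)
    b0[1] <- log((sum(y) + 0.5) / sum(exp(off)))
    b0
  } else beta_init
  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  pdev_of <- function(beta, mu) {
    -2 * sum(stats::dpois(y, mu, log = TRUE)) +
      drop(crossprod(beta, st$S %*% beta))
  }
  pdev <- pdev_of(beta, mu)
  dev_trace <- pdev
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(ctl$inner_maxit)) {
    w <- pmax(mu, 1e-10)
    z <- (eta - off) + (y - mu) / w
    sw <- sqrt(w)
    A <- crossprod(X * sw) + st$S
    b <- crossprod(X, w * z)
    ch <- tryCatch(chol(A), error = function(e)
      chol(A + diag(1e-8 * max(diag(A)), p)))
    beta_new <- drop(backsolve(ch, forwardsolve(t(ch), b)))
    # step-halving on penalized-deviance increase
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try) + off
      mu_try <- exp(pmin(eta_try, 700))
      pdev_try <- pdev_of(beta_try, mu_try)
      if (is.finite(pdev_try) && pdev_try <= pdev + 1e-10) break
      step <- step / 2
      if (step < 2^-30) { beta_try <- beta; eta_try <- eta; mu_try <- mu; pdev_try <- pdev; break }
    }
    rel <- abs(pdev - pdev_try) / (abs(pdev) + 0.1)
    beta <- beta_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
    dev_trace <- c(dev_trace, pdev)
    if (rel < ctl$inner_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("penalized IRLS failed to converge in %d iterations (last rel. change %.3g); trace: %s",
                 ctl$inner_maxit, rel,
                 paste(signif(utils::head(rev(dev_trace), 5), 8), collapse = " <- ")))
  w <- pmax(mu, 1e-10)
  A0 <- crossprod(X * sqrt(w))          # unpenalized information
  A <- A0 + st$S
  ch <- chol(A)
  Hinv <- chol2inv(ch)
  grad <- drop(crossprod(X, y - mu)) - drop(st$S %*% beta)
  list(beta = setNames(beta, colnames(X)), mu = mu, eta = eta, Hinv = Hinv,
       A0 = A0, pdev = pdev, iter = iter, grad_norm = sqrt(sum(grad^2)),
       dev_trace = dev_trace)
}

#' Fit the STAR model with REML-estimated smoothing variances
#'
#' Outer loop of the empirical-Bayes fit: alternates penalized IRLS (inner
#' loop) with Fellner-Schall REML updates of each penalized block's variance
#' `tau^2_j`, optionally damped by an inverse-gamma IG(a, b) prior on the
#' variances (default IG(0.001, 0.001), a near-flat prior that stabilizes
#' the update when a block's coefficients are close to zero). At
#' convergence the returned posterior covariance is the inverse penalized
#' information, and per-block effective degrees of freedom are traces of the
#' corresponding hat-operator blocks.
#'
#' @inheritParams fit_pirls
#' @param variances optional starting variances (default `tau2_init` for
#'   every penalized block).
#' @return An object of class `star_fit`: list with `coefficients`, `cov`
#'   (posterior covariance), `se`, `variances`, `edf` (per block),
#'   `edf_total`, `loglik`, `aic`, `deviance`, `fitted`, `inner_iter`,
#'   `outer_iter`, `converged`, `grad_norm`, `blocks`, `meta`.
#' @export
fit_star <- function(design, variances = NULL, control = list()) {
  ctl <- utils::modifyList(default_control(), control)
  st <- .pirls_state(design, variances, ctl)
  if (!length(st$pen_blocks)) {            # plain GLM, no outer loop
    res <- .pirls_run(st, ctl)
    return(.as_star_fit(design, res, st, outer_iter = 0L, converged_outer = TRUE))
  }
  tau2 <- st$variances
  res <- NULL
  converged <- FALSE
  outer <- 0L
  for (outer in seq_len(ctl$outer_maxit)) {
    res <- .pirls_run(st, ctl, beta_init = if (is.null(res)) NULL else res$beta)
    tau2_new <- tau2
    for (b in st$pen_blocks) {
      idx <- b$idx
      bj <- res$beta[idx]
      bSb <- drop(crossprod(bj, b$penalty %*% bj))
      trHS <- sum(res$Hinv[idx, idx] * b$penalty)
      denom <- b$rank - trHS / tau2[[b$name]]
      denom <- max(denom, 1e-8)
      tau2_new[[b$name]] <- if (ctl$use_ig)
        (bSb + 2 * ctl$ig_b) / (denom + 2 * ctl$ig_a) else bSb / denom
      if (tau2_new[[b$name]] < ctl$tau2_floor) {
        warning(sprintf("variance of block '%s' collapsed below floor; clamped", b$name))
        tau2_new[[b$name]] <- ctl$tau2_floor
      }
      tau2_new[[b$name]] <- min(tau2_new[[b$name]], ctl$tau2_cap)
    }
    rel <- max(abs(tau2_new - tau2) / (tau2 + 1e-12))
    tau2 <- tau2_new
    st <- .pirls_state(design, tau2, ctl)
    if (rel < ctl$outer_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("REML variance loop did not converge in %d outer iterations (last rel. change %.3g)",
                 ctl$outer_maxit, rel))
  res <- .pirls_run(st, ctl, beta_init = res$beta)
  .as_star_fit(design, res, st, outer_iter = outer, converged_outer = TRUE)
}

.as_star_fit <- function(design, res, st, outer_iter, converged_outer) {
  edf_diag <- rowSums(res$Hinv * res$A0)   # diag of Hinv %*% A0 (both symmetric)
  edf <- vapply(design$blocks, function(b) sum(edf_diag[b$idx]), numeric(1))
  names(edf) <- vapply(design$blocks, `[[`, "", "name")
  edf_total <- sum(edf)
  loglik <- sum(stats::dpois(design$y, res$mu, log = TRUE))
  ysat <- design$y
  dev <- 2 * sum(ifelse(ysat > 0, ysat * log(ysat / res$mu), 0) - (ysat - res$mu))
  structure(list(
    coefficients = res$beta,
    cov = res$Hinv,
    se = setNames(sqrt(pmax(diag(res$Hinv), 0)), names(res$beta)),
    variances = st$variances,
    edf = edf, edf_total = edf_total,
    loglik = loglik, aic = -2 * loglik + 2 * edf_total, deviance = dev,
    fitted = res$mu,
    inner_iter = res$iter, outer_iter = outer_iter,
    converged = isTRUE(converged_outer) || is.na(converged_outer),
    grad_norm = res$grad_norm,
    blocks = design$blocks, meta = design$meta,
    n = length(design$y)),
    class = "star_fit")
}

#' @export
print.star_fit <- function(x, ...) {
  cat("Poisson STAR fit:", x$n, "observations,",
      length(x$coefficients), "coefficients\n")
  cat(sprintf("  log-likelihood %.2f | edf %.2f | AIC %.2f\n",
              x$loglik, x$edf_total, x$aic))
  if (length(x$variances))
    cat("  variances:", paste(sprintf("%s=%.4g", names(x$variances), x$variances),
                              collapse = ", "), "\n")
  fixed <- x$blocks[[1]]$idx
  print(round(cbind(estimate = x$coefficients[fixed], se = x$se[fixed]), 4))
  invisible(x)
}

#' Akaike information criterion of a STAR fit
#'
#' `AIC = -2 loglik + 2 edf_total`, with total effective degrees of freedom
#' the trace of the hat operator (unpenalized columns contribute 1 each,
#' penalized blocks their partial hat-trace).
#'
#' @param object a [star_fit][fit_star].
#' @param ... unused.
#' @param k penalty per edf (default 2).
#' @return numeric AIC.
#' @export
AIC.star_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$edf_total
}

#' @export
logLik.star_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf_total, class = "logLik")
}

#' @export
coef.star_fit <- function(object, ...) object$coefficients

#' @export
vcov.star_fit <- function(object, ...) object$cov
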