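# Marginal maximum likelihood estimation of CDMs by EM over the 2^K
# latent classes, plus fit indices and information-criterion selection.

# Per-person x per-class log-likelihood matrix. Missing scores contribute
# nothing. Logs are floored so that structurally impossible classes get a
# very large negative (finite) value instead of -Inf.
loglik_matrix <- function(scores, probs) {
  obs <- !is.na(scores)
  x1 <- ifelse(obs & scores == 1L, 1, 0)
  x0 <- ifelse(obs & scores == 0L, 1, 0)
  logp <- log(pmax(probs, 1e-300))
  log1p_ <- log(pmax(1 - probs, 1e-300))
  x1 %*% logp + x0 %*% log1p_
}

#' Marginal log-likelihood of a CDM
#'
#' The observed-data log-likelihood of the latent-class model: for each
#' person, the log of the class-distribution-weighted sum over all `2^K`
#' attribute patterns of the product of Bernoulli item likelihoods. Missing
#' scores are skipped person-by-item.
#'
#' @param responses A [response_data] object.
#' @param q A [q_matrix] aligned with the response items.
#' @param model A [model_spec] or name.
#' @param item_params List of per-item parameter blocks.
#' @param class_dist Probability vector over the `2^K` patterns in
#'   canonical index order.
#' @return The scalar log-likelihood.
#' @export
cdm_loglik <- function(responses, q, model, item_params, class_dist) {
  check_alignment(responses, q)
  check_class_dist(class_dist, ncol(q))
  if (any(rowSums(!is.na(responses$scores)) == 0L)) {
    stop("at least one person has all items missing")
  }
  probs <- class_success_probs(model, item_params, q)
  ll <- loglik_matrix(responses$scores, probs)
  sum(log_sum_exp_rows(sweep(ll, 2L, log(pmax(class_dist, 1e-300)), `+`)))
}

log_sum_exp_rows <- function(a) {
  m <- apply(a, 1L, max)
  m + log(rowSums(exp(a - m)))
}

check_class_dist <- function(class_dist, k) {
  if (length(class_dist) != 2^k || any(class_dist < 0) ||
      abs(sum(class_dist) - 1) > 1e-10) {
    stop("class_dist must be a probability vector over the 2^K patterns")
  }
  invisible(class_dist)
}

check_alignment <- function(responses, q) {
  if (ncol(responses$scores) != nrow(q)) {
    stop("response data have ", ncol(responses$scores),
         " items but the Q-matrix has ", nrow(q))
  }
  ri <- responses$item_ids
  qi <- rownames(q)
  default_r <- identical(ri, paste0("item", seq_along(ri)))
  default_q <- identical(qi, paste0("item", seq_along(qi)))
  if (!default_r && !default_q && !identical(ri, qi)) {
    stop("item ids of the responses do not match the Q-matrix rows in order")
  }
  invisible(TRUE)
}

# Posterior class-membership probabilities given parameters; rows sum to 1.
posterior_matrix <- function(scores, probs, class_dist) {
  a <- sweep(loglik_matrix(scores, probs), 2L,
             log(pmax(class_dist, 1e-300)), `+`)
  m <- apply(a, 1L, max)
  w <- exp(a - m)
  w / rowSums(w)
}

#' Fit a CDM by EM marginal maximum likelihood
#'
#' E-step: posterior class-membership probabilities under the current
#' parameters. M-step: the class distribution is the mean posterior; for
#' identity-link structures (DINA, DINO, saturated G-DINA) item parameters
#' update in closed form as posterior-weighted success proportions per
#' reduced pattern (DINA/DINO pool the reduced patterns into their two
#' groups); the additive models (A-CDM, LLM, RRUM) maximize the expected
#' complete-data log-likelihood numerically under their link-scale
#' constraints. Iterates until the largest absolute change in the implied
#' success probabilities and class proportions, or the log-likelihood
#' change, drops below `tol`. The observed log-likelihood is non-decreasing
#' across iterations (generalized EM: a numerical M-step update is only
#' accepted when it does not decrease the expected complete-data
#' log-likelihood).
#'
#' @inheritParams cdm_loglik
#' @param tol Convergence tolerance on the maximum parameter change
#'   (default 1e-4).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param monotone Enforce that mastering an attribute never lowers the
#'   success probability. Default `NULL`: on for the additive models, off
#'   for the others (DINA/DINO and the saturated model are unconstrained,
#'   the standard convention).
#' @param init Optional starting `item_params` (default [init_item_params]).
#' @param seed Optional seed jittering the starting values uniformly by up
#'   to `±0.01` on the probability scale; `NULL` keeps the
#'   deterministic start.
#' @param by_group Estimate a separate latent-class distribution per group
#'   (multigroup structural model) while keeping the item parameters
#'   pooled across groups. Requires group labels on `responses`. Each
#'   group's distribution then acts as that group's prior in person
#'   classification, which avoids the shrinkage of group-specific pattern
#'   frequencies toward the pooled average. Default `FALSE`: one common
#'   distribution.
#' @return An object of class `cdm_fit` with the fitted `item_params`,
#'   `class_dist` (a probability vector, or a groups-by-classes matrix
#'   when `by_group = TRUE`), `loglik`, `deviance`, `npar`, `aic`, `bic`,
#'   `n_used`, `converged`, `iterations`, the per-iteration
#'   `loglik_trace`, and the inputs `model` and `q`.
#' @export
em_fit <- function(responses, q, model, tol = 1e-4, max_iter = 1000,
                   monotone = NULL, init = NULL, seed = NULL,
                   by_group = FALSE) {
  model <- as_model_spec(model)
  check_alignment(responses, q)
  scores <- responses$scores
  n <- nrow(scores)
  if (n < 1L) stop("no persons to fit")
  if (any(rowSums(!is.na(scores)) == 0L)) {
    stop("at least one person has all items missing")
  }
  k <- ncol(q)
  n_class <- 2^k
  if (is.null(monotone)) monotone <- model$structure == "additive"

  item_means <- colMeans(scores, na.rm = TRUE)
  flat <- item_means %in% c(0, 1)
  if (any(flat)) {
    warning("item(s) with no score variation: ",
            paste(colnames(scores)[flat], collapse = ", "),
            "; success probabilities will sit at the boundary guard")
  }

  if (by_group && is.null(responses$group)) {
    stop("by_group = TRUE requires group labels on the responses")
  }
  groups <- if (by_group) unique(responses$group) else "all"
  gidx <- if (by_group) match(responses$group, groups) else rep(1L, n)
  n_groups <- length(groups)

  npar <- count_parameters(model, q) + (n_groups - 1L) * (n_class - 1L)
  degenerate <- npar > n
  if (degenerate) {
    message("model has ", npar, " free parameters but only ", n,
            " persons; the fit is degenerate and reported as such")
  }

  params <- if (is.null(init)) init_item_params(model, q) else init
  if (!is.null(seed)) {
    params <- jitter_params(params, model, seed)
  }
  class_dist <- matrix(1 / n_class, n_groups, n_class)

  obs <- !is.na(scores)
  x1 <- ifelse(obs & scores == 1L, 1, 0)

  # class -> reduced-pattern index per item, fixed by the Q-matrix
  patterns <- attribute_patterns(k)
  red_index <- lapply(seq_len(nrow(q)), function(j) {
    req <- which(q[j, ] == 1L)
    as.integer(patterns[, req, drop = FALSE] %*% 2^((length(req) - 1):0))
  })

  probs <- class_success_probs(model, params, q)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step
    a <- loglik_matrix(scores, probs) +
      log(pmax(class_dist, 1e-300))[gidx, , drop = FALSE]
    m <- apply(a, 1L, max)
    w <- exp(a - m)
    rs <- rowSums(w)
    ll <- sum(m + log(rs))
    trace <- c(trace, ll)
    post <- w / rs

    # M-step
    class_dist_new <- class_dist
    for (g in seq_len(n_groups)) {
      class_dist_new[g, ] <- colMeans(post[gidx == g, , drop = FALSE])
    }
    params_new <- params
    for (j in seq_len(nrow(q))) {
      r_c <- as.numeric(crossprod(post, x1[, j]))
      n_c <- as.numeric(crossprod(post, as.numeric(obs[, j])))
      idx <- red_index[[j]]
      r_l <- tapply_sum(r_c, idx)
      n_l <- tapply_sum(n_c, idx)
      kj <- sum(q[j, ])
      params_new[[j]] <- m_step_item(model, params[[j]], kj, r_l, n_l,
                                     monotone)
    }
    probs_new <- class_success_probs(model, params_new, q)

    delta_par <- max(abs(probs_new - probs), abs(class_dist_new - class_dist))
    delta_ll <- ll - ll_old
    probs <- probs_new
    params <- params_new
    class_dist <- class_dist_new
    ll_old <- ll
    if (delta_par < tol || abs(delta_ll) < tol) {
      converged <- TRUE
      break
    }
  }

  loglik <- sum(log_sum_exp_rows(
    loglik_matrix(scores, probs) +
      log(pmax(class_dist, 1e-300))[gidx, , drop = FALSE]))
  colnames(class_dist) <- rownames(patterns)
  rownames(class_dist) <- groups
  if (!by_group) class_dist <- class_dist[1L, ]
  ic <- fit_indices(loglik, npar, n)
  structure(list(model = model, q = q, item_params = params,
                 class_dist = class_dist, by_group = by_group,
                 loglik = loglik,
                 deviance = ic$deviance, npar = npar, aic = ic$aic,
                 bic = ic$bic, n_used = n, converged = converged,
                 iterations = iter, loglik_trace = trace,
                 degenerate = degenerate, monotone = monotone),
            class = "cdm_fit")
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat(sprintf("<cdm_fit> %s: n = %d, loglik = %.2f, npar = %d, AIC = %.1f, BIC = %.1f\n",
              x$model$name, x$n_used, x$loglik, x$npar, x$aic, x$bic))
  cat(sprintf("  %s after %d EM iterations\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

tapply_sum <- function(values, index) {
  out <- numeric(max(index) + 1L)
  for (i in seq_along(values)) {
    out[index[i] + 1L] <- out[index[i] + 1L] + values[i]
  }
  out
}

p_lo <- 1e-4
p_hi <- 1 - 1e-4

clip_p <- function(p) pmin(pmax(p, p_lo), p_hi)

# One item's M-step. r_l / n_l are posterior-expected correct counts and
# totals per reduced pattern (canonical order over the 2^kj patterns).
m_step_item <- function(model, par, kj, r_l, n_l, monotone) {
  switch(model$structure,
    saturated = {
      p_old <- par$prob
      p_new <- ifelse(n_l > 1e-12, r_l / pmax(n_l, 1e-12), p_old)
      saturated_params(clip_p(p_new))
    },
    conjunctive = {
      full <- length(r_l)   # index of the all-ones reduced pattern
      g <- sum(r_l[-full]) / max(sum(n_l[-full]), 1e-12)
      s <- 1 - r_l[full] / max(n_l[full], 1e-12)
      gs_params(clip_p(g), clip_p(s))
    },
    disjunctive = {
      none <- 1L            # index of the all-zero reduced pattern
      g <- r_l[none] / max(n_l[none], 1e-12)
      s <- 1 - sum(r_l[-none]) / max(sum(n_l[-none]), 1e-12)
      gs_params(clip_p(g), clip_p(s))
    },
    additive = m_step_additive(model, par, kj, r_l, n_l, monotone)
  )
}

# Expected complete-data log-likelihood for one additive item, as a
# function of theta = c(delta0, delta); maximized numerically.
m_step_additive <- function(model, par, kj, r_l, n_l, monotone) {
  red <- attribute_patterns(kj)
  x <- cbind(1, red)
  inv <- linkinv_fun(model$link)
  obj <- function(theta) {
    p <- clip_p(inv(as.numeric(x %*% theta)))
    -sum(r_l * log(p) + (n_l - r_l) * log(1 - p))
  }
  grad <- function(theta) {
    eta <- as.numeric(x %*% theta)
    p <- clip_p(inv(eta))
    dpdeta <- switch(model$link, identity = rep(1, length(p)),
                     logit = p * (1 - p), log = p)
    w <- (r_l - n_l * p) / (p * (1 - p)) * dpdeta
    -as.numeric(crossprod(x, w))
  }
  theta0 <- c(par$delta0, par$delta)
  theta1 <- tryCatch({
    if (monotone) {
      cons <- additive_constraints(model$link, kj)
      start <- repair_interior(theta0, cons$ui, cons$ci)
      res <- stats::constrOptim(start, f = obj, grad = grad,
                                ui = cons$ui, ci = cons$ci,
                                method = "BFGS", mu = 1e-6,
                                outer.iterations = 25, outer.eps = 1e-8,
                                control = list(maxit = 100))
      res$par
    } else {
      stats::optim(theta0, obj, grad, method = "BFGS",
                   control = list(maxit = 100))$par
    }
  }, error = function(e) theta0)
  # generalized-EM guard: never accept an update that lowers the expected
  # complete-data log-likelihood
  if (obj(theta1) <= obj(theta0)) {
    additive_params(theta1[1L], theta1[-1L])
  } else {
    par
  }
}

# Linear inequality constraints ui %*% theta >= ci keeping an additive
# item's probabilities inside [p_lo, p_hi] and its main effects >= 0.
additive_constraints <- function(link, kj) {
  eye <- diag(kj + 1L)
  main <- eye[-1L, , drop = FALSE]           # delta_k >= 0
  switch(link,
    logit = list(ui = main, ci = rep(0, kj)),
    identity = list(
      ui = rbind(main, eye[1L, ], -rep(1, kj + 1L)),
      ci = c(rep(0, kj), p_lo, -(1 - p_lo))),
    log = list(
      ui = rbind(main, -rep(1, kj + 1L)),
      ci = c(rep(0, kj), -log(1 - p_lo))))
}

# Pull a start point strictly inside the feasible region for constrOptim.
repair_interior <- function(theta, ui, ci, margin = 1e-7) {
  for (pass in 1:50) {
    slack <- as.numeric(ui %*% theta) - ci
    i <- which.min(slack)
    if (slack[i] > margin) break
    dir <- ui[i, ] / sum(ui[i, ]^2)
    theta <- theta + dir * (margin * 2 - slack[i])
  }
  theta
}

jitter_params <- function(params, model, seed) {
  model <- as_model_spec(model)
  withr_seed <- local_seed(seed)
  on.exit(withr_seed())
  lapply(params, function(par) {
    u <- function(n) stats::runif(n, -0.01, 0.01)
    switch(attr(par, "kind"),
      gs = gs_params(clip_p(par$guess + u(1)), clip_p(par$slip + u(1))),
      additive = additive_params(par$delta0 + u(1),
                                 pmax(par$delta + u(length(par$delta)), 0)),
      saturated = saturated_params(clip_p(par$prob + u(length(par$prob)))))
  })
}

# Set the RNG seed locally; returns a restore function.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Deviance, AIC and BIC
#'
#' `deviance = -2 loglik`, `AIC = deviance + 2 npar`,
#' `BIC = deviance + npar * log(n)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param npar Number of free parameters.
#' @param n Number of persons fitted.
#' @return A list with `deviance`, `aic`, `bic`.
#' @export
fit_indices <- function(loglik, npar, n) {
  stopifnot(n >= 1)
  dev <- -2 * loglik
  list(deviance = dev, aic = dev + 2 * npar, bic = dev + npar * log(n))
}

#' Fit statistics records for precomputed model comparisons
#'
#' Builds lightweight fit records from a published or externally computed
#' comparison table (model name, deviance, AIC, BIC), so that
#' [select_model()] and [model_comparison()] work on printed tables as well
#' as on freshly fitted [em_fit] objects. The implied parameter count is
#' recovered as `(AIC - deviance) / 2`.
#'
#' @param table A data frame with columns `model`, `deviance`, `aic`, `bic`.
#' @param n_used Common person count, if known (default `NA`).
#' @return A list of objects of class `cdm_fit_stats`.
#' @export
fit_stats <- function(table, n_used = NA_integer_) {
  stopifnot(all(c("model", "deviance", "aic", "bic") %in% names(table)))
  lapply(seq_len(nrow(table)), function(i) {
    structure(list(model = list(name = as.character(table$model[i])),
                   deviance = table$deviance[i], aic = table$aic[i],
                   bic = table$bic[i],
                   npar = (table$aic[i] - table$deviance[i]) / 2,
                   n_used = n_used),
              class = "cdm_fit_stats")
  })
}

#' Model comparison and selection by information criteria
#'
#' `model_comparison()` tabulates deviance, AIC and BIC for a list of fits;
#' `select_model()` returns the fit with the lowest BIC (the preferred
#' criterion), breaking ties by lowest AIC, then fewest parameters.
#'
#' @param fits Non-empty list of [em_fit] results and/or [fit_stats]
#'   records, all fitted on the same data.
#' @return `model_comparison()`: a data frame with columns `model`,
#'   `deviance`, `aic`, `bic`, `npar`, `selected`. `select_model()`: the
#'   selected fit object.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1L)
  n_used <- vapply(fits, function(f) as.numeric(f$n_used), numeric(1L))
  known <- n_used[!is.na(n_used)]
  if (length(unique(known)) > 1L) {
    stop("fits were not computed on the same number of persons")
  }
  ord <- order(vapply(fits, function(f) f$bic, numeric(1L)),
               vapply(fits, function(f) f$aic, numeric(1L)),
               vapply(fits, function(f) f$npar, numeric(1L)))
  fits[[ord[1L]]]
}

#' @rdname select_model
#' @export
model_comparison <- function(fits) {
  best <- select_model(fits)
  out <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1L)),
    deviance = vapply(fits, function(f) f$deviance, numeric(1L)),
    aic = vapply(fits, function(f) f$aic, numeric(1L)),
    bic = vapply(fits, function(f) f$bic, numeric(1L)),
    npar = vapply(fits, function(f) as.numeric(f$npar), numeric(1L))
  )
  out$selected <- out$model == best$model$name & out$bic == best$bic
  out
}
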