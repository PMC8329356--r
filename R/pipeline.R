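# Pipeline drivers tying the stages together: fit + compare models,
# classify respondents, extract trajectories — each writing the CSV/DOT
# reports its stage of the analysis produces. The numbered scripts under
# analysis/ are thin narrative wrappers around these functions.

#' Path to a packaged data file
#'
#' The package ships small plain-text copies of the published summary
#' tables of the PISA 2012 statistics-item study (Q-matrix of the nine
#' shared items over four attributes, number-correct score counts, the
#' model-fit comparison statistics and the per-country top-five
#' attribute-pattern tables), which serve as worked-example inputs.
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
cdmtraj_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cdmtraj")))
  }
  path <- system.file("extdata", file, package = "cdmtraj")
  if (!nzchar(path)) stop("no packaged file ", sQuote(file))
  path
}

#' Fit several CDMs and write a comparison report
#'
#' Fits every requested model to the same data, writes a comparison table
#' (model, deviance, AIC, BIC) as CSV, and serializes the selected
#' (lowest-BIC) fit as structured JSON.
#'
#' @param responses A [response_data] object.
#' @param q A [q_matrix].
#' @param models Character vector of model names (non-empty).
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [em_fit] (e.g. `tol`, `max_iter`, `seed`).
#' @return Invisibly, a list with `fits`, `comparison` (data frame) and
#'   `best` (the selected fit).
#' @export
run_fit_pipeline <- function(responses, q, models, out_dir, ...) {
  if (length(models) == 0L) stop("no models requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(models, function(m) em_fit(responses, q, m, ...))
  names(fits) <- toupper(models)
  comparison <- model_comparison(fits)
  best <- select_model(fits)
  utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  write_fit(best, file.path(out_dir, "best_fit.json"))
  write_item_params(best$model, best$item_params, q,
                    file.path(out_dir, "best_item_params.json"))
  invisible(list(fits = fits, comparison = comparison, best = best))
}

#' Classify respondents and write group summaries
#'
#' Writes the per-person mastery profiles, the group-by-attribute mean EAP
#' table, and the per-group top-`k` pattern frequency table.
#'
#' @inheritParams run_fit_pipeline
#' @param fit A fitted model ([em_fit] result or `best_fit.json` path).
#' @param method,threshold Passed to [mastery_profiles].
#' @param top_k Patterns kept per group in the frequency report
#'   (default 5).
#' @return Invisibly, a list with `profiles`, `group_means`, `frequencies`
#'   (unrestricted) and `top_patterns`.
#' @export
run_classify_pipeline <- function(responses, fit, out_dir, method = "EAP",
                                  threshold = 0.5, top_k = 5) {
  if (is.character(fit)) fit <- read_fit(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- mastery_profiles(responses, fit, method = method,
                               threshold = threshold)
  group_means <- group_attribute_means(profiles)
  freq <- pattern_frequencies(profiles)
  top <- pattern_frequencies(profiles, top_k = top_k)
  utils::write.csv(profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(group_means, file.path(out_dir, "group_attribute_means.csv"),
                   row.names = FALSE)
  utils::write.csv(top, file.path(out_dir, "top_patterns.csv"),
                   row.names = FALSE)
  invisible(list(profiles = profiles, group_means = group_means,
                 frequencies = freq, top_patterns = top))
}

#' Extract and report learning trajectories per group
#'
#' Accepts a pattern frequency table (a [pattern_frequencies] data frame
#' or a CSV path with columns `group`, `pattern`, `proportion` — which is
#' how published top-five tables enter the pipeline without raw response
#' data), extracts each group's trajectory, writes a per-group DOT graph,
#' a trajectory summary CSV (group, level, state, frequency, secondary
#' state, ratio) and, with more than one group, a cross-group comparison.
#'
#' @param frequencies A [pattern_frequencies] data frame or a CSV path.
#' @param out_dir Output directory.
#' @param attribute_names Optional attribute labels for reporting.
#' @param ... Passed to [extract_trajectory] (`secondary_ratio`,
#'   `restrict_top_k`, `scorer`).
#' @return Invisibly, a list with `trajectories`, `summary` (long data
#'   frame) and `comparison` ([compare_trajectories] output or NULL for a
#'   single group).
#' @export
run_trajectory_pipeline <- function(frequencies, out_dir,
                                    attribute_names = NULL, ...) {
  if (is.character(frequencies)) {
    frequencies <- utils::read.csv(frequencies, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  }
  need <- c("group", "pattern")
  if (!all(need %in% colnames(frequencies))) {
    stop("frequency table must have columns `group` and `pattern` ",
         "(plus `proportion`); missing: ",
         paste(setdiff(need, colnames(frequencies)), collapse = ", "))
  }
  bad <- which(is.na(frequencies$pattern) | !grepl("[01]", frequencies$pattern))
  if (length(bad)) {
    stop("malformed pattern in frequency table row ", bad[1L])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trajectories <- group_trajectories(frequencies,
                                     attribute_names = attribute_names, ...)
  long <- do.call(rbind, lapply(names(trajectories), function(g) {
    tr <- trajectories[[g]]
    st <- tr$steps
    data.frame(group = g, level = st$level, state = st$state,
               frequency = st$freq,
               secondary_state = ifelse(st$secondary, st$runner_up,
                                        NA_character_),
               secondary_frequency = ifelse(st$secondary, st$runner_freq,
                                            NA_real_),
               ratio = st$ratio, unsupported = st$unsupported,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(out_dir, "trajectory_summary.csv"),
                   row.names = FALSE)
  for (g in names(trajectories)) {
    export_graph(trajectories[[g]], "DOT",
                 path = file.path(out_dir, paste0("trajectory_",
                                                  gsub("\\W+", "_", g),
                                                  ".dot")))
  }
  comparison <- NULL
  if (length(trajectories) > 1L) {
    comparison <- compare_trajectories(trajectories)
    utils::write.csv(comparison$summary,
                     file.path(out_dir, "trajectory_comparison.csv"),
                     row.names = FALSE)
  }
  invisible(list(trajectories = trajectories, summary = long,
                 comparison = comparison))
}

#' Serialize / restore a fitted model
#'
#' Structured JSON round-trip of an [em_fit] result (model, Q-matrix, item
#' parameters, class distribution and fit statistics).
#'
#' @param fit An [em_fit] result.
#' @param path JSON file path.
#' @export
write_fit <- function(fit, path) {
  q <- fit$q
  pars <- lapply(fit$item_params, function(par) {
    c(list(kind = attr(par, "kind")), unclass(par))
  })
  cd <- fit$class_dist
  cd_out <- if (is.matrix(cd)) {
    list(groups = rownames(cd), probs = unname(apply(cd, 1L, as.list)))
  } else {
    as.list(cd)
  }
  obj <- list(model = fit$model$name, item_ids = rownames(q),
              attribute_names = colnames(q), q = unclass(unname(q)),
              item_params = pars,
              class_dist = cd_out,
              loglik = fit$loglik, deviance = fit$deviance,
              npar = fit$npar, aic = fit$aic, bic = fit$bic,
              n_used = fit$n_used, converged = fit$converged,
              iterations = fit$iterations, monotone = fit$monotone)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  q <- q_matrix(obj$q, item_ids = obj$item_ids,
                attribute_names = obj$attribute_names)
  pars <- lapply(obj$item_params, function(p) {
    switch(p$kind,
           gs = gs_params(p$guess, p$slip),
           additive = additive_params(p$delta0, unlist(p$delta)),
           saturated = saturated_params(unlist(p$prob)))
  })
  cd <- obj$class_dist
  if (!is.null(cd$groups)) {
    cd <- matrix(unlist(cd$probs), nrow = length(cd$groups), byrow = TRUE,
                 dimnames = list(cd$groups,
                                 rownames(attribute_patterns(ncol(q)))))
  } else {
    cd <- unlist(cd)
  }
  structure(list(model = model_spec(obj$model), q = q, item_params = pars,
                 class_dist = cd, loglik = obj$loglik,
                 deviance = obj$deviance, npar = obj$npar, aic = obj$aic,
                 bic = obj$bic, n_used = obj$n_used,
                 converged = obj$converged, iterations = obj$iterations,
                 loglik_trace = NULL, degenerate = NA,
                 monotone = obj$monotone),
            class = "cdm_fit")
}
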