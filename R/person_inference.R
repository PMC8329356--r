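# Person-level attribute inference: posterior class probabilities,
# EAP marginals, pattern classification, and group-level summaries.

#' Posterior class probabilities for each respondent
#'
#' Bayes rule with the fitted latent-class distribution as the prior: the
#' posterior probability of class `c` is proportional to the class weight
#' times the likelihood of the person's observed responses under class `c`.
#'
#' @param responses A [response_data] object.
#' @param fit A [em_fit] result on a compatible item set.
#' @return A persons-by-`2^K` matrix; rows sum to 1, columns are labelled
#'   with the pattern tuples in canonical index order.
#' @export
posterior_classes <- function(responses, fit) {
  check_alignment(responses, fit$q)
  if (any(rowSums(!is.na(responses$scores)) == 0L)) {
    stop("at least one person has all items missing")
  }
  probs <- class_success_probs(fit$model, fit$item_params, fit$q)
  if (is.matrix(fit$class_dist)) {
    # multigroup fit: each person's prior is their group's distribution
    if (is.null(responses$group)) {
      stop("the fit has group-specific class distributions but the responses carry no group labels")
    }
    gidx <- match(responses$group, rownames(fit$class_dist))
    if (anyNA(gidx)) {
      stop("group(s) not present in the fit: ",
           paste(unique(responses$group[is.na(gidx)]), collapse = ", "))
    }
    a <- loglik_matrix(responses$scores, probs) +
      log(pmax(fit$class_dist, 1e-300))[gidx, , drop = FALSE]
    m <- apply(a, 1L, max)
    w <- exp(a - m)
    post <- w / rowSums(w)
  } else {
    post <- posterior_matrix(responses$scores, probs, fit$class_dist)
  }
  dimnames(post) <- list(responses$person_ids,
                         rownames(attribute_patterns(ncol(fit$q))))
  post
}

#' EAP marginal mastery probabilities
#'
#' The expected-a-posteriori probability that a person masters attribute
#' `k` is the total posterior mass of the classes whose pattern has bit `k`
#' set.
#'
#' @param posterior A persons-by-`2^K` posterior matrix
#'   (from [posterior_classes]).
#' @return A persons-by-`K` matrix of marginal mastery probabilities.
#' @export
eap_mastery <- function(posterior) {
  k <- round(log2(ncol(posterior)))
  stopifnot(2^k == ncol(posterior))
  posterior %*% attribute_patterns(k)
}

#' Classify marginal probabilities into an attribute pattern
#'
#' Bit `k` is 1 exactly when the marginal mastery probability reaches the
#' threshold; a probability exactly at the threshold counts as mastered.
#'
#' @param marginals A numeric vector of length `K`, or a persons-by-`K`
#'   matrix.
#' @param threshold Mastery cut-off (default 0.5).
#' @return An integer 0/1 vector or matrix shaped like `marginals`.
#' @export
classify_mastery <- function(marginals, threshold = 0.5) {
  out <- ifelse(marginals >= threshold, 1L, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Per-person mastery profiles
#'
#' Runs the full person-inference chain: posterior classes, EAP marginals,
#' and pattern classification. `method = "EAP"` (the default) thresholds
#' the marginals; `"MAP"` takes the posterior-mode pattern; `"MLE"` the
#' likelihood-mode pattern (uniform prior over classes).
#'
#' @inheritParams posterior_classes
#' @param method One of `"EAP"`, `"MAP"`, `"MLE"`.
#' @param threshold EAP mastery threshold (default 0.5).
#' @return A data frame of class `mastery_profiles`: `person_id`, `group`
#'   (if present), one `prob_<attribute>` column per attribute, and
#'   `pattern` (the tuple label of the classified pattern).
#' @export
mastery_profiles <- function(responses, fit, method = c("EAP", "MAP", "MLE"),
                             threshold = 0.5) {
  method <- match.arg(method)
  post <- posterior_classes(responses, fit)
  marg <- eap_mastery(post)
  k <- ncol(marg)
  patterns <- attribute_patterns(k)
  bits <- switch(method,
    EAP = classify_mastery(marg, threshold),
    MAP = patterns[max.col(post, ties.method = "first"), , drop = FALSE],
    MLE = {
      probs <- class_success_probs(fit$model, fit$item_params, fit$q)
      lm_ <- loglik_matrix(responses$scores, probs)
      patterns[max.col(lm_, ties.method = "first"), , drop = FALSE]
    })
  out <- data.frame(person_id = responses$person_ids,
                    stringsAsFactors = FALSE)
  if (!is.null(responses$group)) out$group <- responses$group
  colnames(marg) <- paste0("prob_", colnames(fit$q))
  out <- cbind(out, as.data.frame(marg, row.names = NULL))
  out$pattern <- apply(bits, 1L, pattern_label)
  attr(out, "attributes") <- colnames(fit$q)
  attr(out, "method") <- method
  class(out) <- c("mastery_profiles", "data.frame")
  out
}

#' Group means of marginal mastery probabilities
#'
#' Arithmetic mean of the EAP marginals per group and attribute — the
#' structure of a country-by-attribute mastery table.
#'
#' @param profiles A [mastery_profiles] data frame (or any data frame with
#'   a `group` column and `prob_*` columns).
#' @param digits Rounding for reporting (default 2); use `NA` to skip.
#' @return A data frame: one row per group, columns `group`, `n`, and one
#'   mean per attribute.
#' @export
group_attribute_means <- function(profiles, digits = 2) {
  if (is.null(profiles$group)) {
    profiles$group <- "all"
  }
  pcols <- grep("^prob_", colnames(profiles), value = TRUE)
  groups <- unique(profiles$group)
  if (any(!nzchar(groups))) stop("empty group label")
  rows <- lapply(groups, function(g) {
    sub <- profiles[profiles$group == g, pcols, drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group ", sQuote(g))
    mu <- colMeans(sub)
    if (!is.na(digits)) mu <- round(mu, digits)
    cbind(data.frame(group = g, n = nrow(sub)), as.data.frame(as.list(mu)))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- sub("^prob_", "", colnames(out))
  rownames(out) <- NULL
  out
}

#' Pattern frequency tables per group
#'
#' Relative frequency of each classified attribute pattern within each
#' group, sorted by descending proportion (ties broken by canonical class
#' index), optionally restricted to the top `k` patterns for reporting —
#' the structure of a "five most frequent patterns per country" table.
#'
#' @param profiles A [mastery_profiles] data frame.
#' @param top_k Keep only the `top_k` most frequent patterns per group
#'   (default `NULL`: all patterns with non-zero frequency).
#' @return A data frame of class `pattern_frequencies` with columns
#'   `group`, `rank`, `pattern`, `proportion`, `count`.
#' @export
pattern_frequencies <- function(profiles, top_k = NULL) {
  if (is.null(profiles$group)) profiles$group <- "all"
  k <- nchar(gsub("[^01]", "", profiles$pattern[1L]))
  rows <- lapply(unique(profiles$group), function(g) {
    pat <- profiles$pattern[profiles$group == g]
    tab <- table(pat)
    prop <- as.numeric(tab) / length(pat)
    idx <- vapply(names(tab), function(p) pattern_index(parse_pattern(p)),
                  numeric(1L))
    ord <- order(-prop, idx)
    d <- data.frame(group = g, rank = seq_along(ord),
                    pattern = names(tab)[ord], proportion = prop[ord],
                    count = as.numeric(tab)[ord], stringsAsFactors = FALSE)
    if (!is.null(top_k)) d <- d[seq_len(min(top_k, nrow(d))), , drop = FALSE]
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "k") <- k
  class(out) <- c("pattern_frequencies", "data.frame")
  out
}
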