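#' Model specifications for the G-DINA family
#'
#' Six dichotomous-response cognitive diagnosis models are supported, each a
#' fixed pairing of a link function and a structural form:
#'
#' * `DINA` — conjunctive, identity link: all required attributes are needed
#'   (and-gate with guess/slip noise).
#' * `DINO` — disjunctive, identity link: any required attribute suffices
#'   (or-gate with guess/slip noise).
#' * `ACDM` — additive on the probability (identity) scale.
#' * `LLM`  — additive on the logit scale (the logit-link G-DINA model with
#'   no interaction terms).
#' * `RRUM` — additive on the log scale (equivalent parameterization of the
#'   reduced reparameterized unified model).
#' * `GDINA` — saturated: one free success probability per reduced pattern
#'   of each item's required attributes; nests all of the above.
#'
#' @param name Model name (case-insensitive), one of the six above.
#' @return An object of class `model_spec` with fields `name`, `link`
#'   (`identity`, `logit` or `log`) and `structure` (`conjunctive`,
#'   `disjunctive`, `additive` or `saturated`).
#' @examples
#' model_spec("LLM")
#' @export
model_spec <- function(name) {
  name <- toupper(as.character(name))
  name <- match.arg(name, c("DINA", "DINO", "ACDM", "LLM", "RRUM", "GDINA"))
  bindings <- list(
    DINA  = c(link = "identity", structure = "conjunctive"),
    DINO  = c(link = "identity", structure = "disjunctive"),
    ACDM  = c(link = "identity", structure = "additive"),
    LLM   = c(link = "logit",    structure = "additive"),
    RRUM  = c(link = "log",      structure = "additive"),
    GDINA = c(link = "identity", structure = "saturated")
  )
  b <- bindings[[name]]
  structure(list(name = name, link = unname(b["link"]),
                 structure = unname(b["structure"])),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s, %s link)\n", x$name, x$structure, x$link))
  invisible(x)
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

link_fun <- function(link) {
  switch(link,
         identity = identity,
         logit = stats::qlogis,
         log = log,
         stop("unknown link ", link))
}

linkinv_fun <- function(link) {
  switch(link,
         identity = identity,
         logit = stats::plogis,
         log = exp,
         stop("unknown link ", link))
}

#' Project a pattern onto an item's required attributes
#'
#' The reduced pattern of a knowledge state with respect to an item is the
#' sub-vector over the attributes that item requires, in attribute order.
#' Two states identical on the required attributes are indistinguishable to
#' the item; every item response function depends on the full pattern only
#' through this projection.
#'
#' @param q_row Binary vector: the item's Q-matrix row (at least one 1).
#' @param pattern Binary vector: a full attribute pattern of the same length.
#' @return Integer 0/1 vector of length `sum(q_row)`.
#' @examples
#' reduced_pattern(c(1, 0, 1, 1), c(1, 1, 0, 1))  # 1 0 1
#' @export
reduced_pattern <- function(q_row, pattern) {
  q_row <- check_bits(q_row)
  pattern <- check_bits(pattern)
  if (length(q_row) != length(pattern)) {
    stop("q_row and pattern must have the same length")
  }
  if (sum(q_row) < 1L) stop("q_row must require at least one attribute")
  pattern[q_row == 1L]
}

#' Item parameter containers
#'
#' One parameter block per item, with the free parameters the model calls
#' for: guess/slip for DINA/DINO; an intercept plus one main effect per
#' required attribute on the link scale for the additive models; a success
#' probability per reduced pattern for the saturated G-DINA.
#'
#' @param guess,slip Numeric in `[0,1]` (DINA/DINO).
#' @return A list of class `item_params` tagged with its kind.
#' @export
gs_params <- function(guess, slip) {
  stopifnot(guess >= 0, guess <= 1, slip >= 0, slip <= 1)
  structure(list(guess = guess, slip = slip),
            class = "item_params", kind = "gs")
}

#' @rdname gs_params
#' @param delta0 Intercept on the link scale.
#' @param delta Numeric vector of main effects, one per required attribute,
#'   in attribute order.
#' @export
additive_params <- function(delta0, delta) {
  structure(list(delta0 = delta0, delta = as.numeric(delta)),
            class = "item_params", kind = "additive")
}

#' @rdname gs_params
#' @param prob Numeric vector of length `2^K_j` of success probabilities,
#'   ordered by the canonical index of the reduced pattern.
#' @export
saturated_params <- function(prob) {
  stopifnot(all(prob >= 0), all(prob <= 1),
            2^round(log2(length(prob))) == length(prob))
  structure(list(prob = as.numeric(prob)),
            class = "item_params", kind = "saturated")
}

#' Item response function
#'
#' Success probability of one item for one knowledge state under a given
#' model. For DINA the probability is `1 - slip` when all required
#' attributes are mastered and `guess` otherwise; for DINO the mastered
#' branch needs any one required attribute. Additive models evaluate the
#' inverse link of `delta0 + sum(delta[k] * alpha[k])` over required
#' attributes; identity and log links error when the implied probability
#' leaves `[0,1]` (no silent clamping). The saturated model looks the
#' reduced pattern up in its probability table.
#'
#' @param model A [model_spec] or model name.
#' @param params An `item_params` block matching the model.
#' @param q_row The item's Q-matrix row.
#' @param pattern Full attribute pattern.
#' @return A probability in `[0,1]`.
#' @examples
#' irf("DINA", gs_params(0.2, 0.1), c(1, 1, 0, 0), c(1, 1, 0, 0))  # 0.9
#' @export
irf <- function(model, params, q_row, pattern) {
  model <- as_model_spec(model)
  red <- reduced_pattern(q_row, pattern)
  irf_reduced(model, params, red)
}

irf_reduced <- function(model, params, red) {
  kind <- attr(params, "kind")
  switch(model$structure,
    conjunctive = {
      stopifnot(kind == "gs")
      if (all(red == 1L)) 1 - params$slip else params$guess
    },
    disjunctive = {
      stopifnot(kind == "gs")
      if (any(red == 1L)) 1 - params$slip else params$guess
    },
    additive = {
      stopifnot(kind == "additive", length(params$delta) == length(red))
      eta <- params$delta0 + sum(params$delta * red)
      p <- linkinv_fun(model$link)(eta)
      if (p < 0 || p > 1 || !is.finite(p)) {
        stop(sprintf("additive %s-link parameters imply success probability %g outside [0,1]",
                     model$link, p))
      }
      p
    },
    saturated = {
      stopifnot(kind == "saturated", length(params$prob) == 2^length(red))
      params$prob[pattern_index(red) + 1L]
    }
  )
}

#' Success probabilities for every latent class
#'
#' Evaluates the item response function of every item at all `2^K`
#' attribute patterns, the quantity the EM algorithm and the simulator both
#' consume.
#'
#' @param model A [model_spec] or name.
#' @param item_params List of `item_params`, one per item.
#' @param q A [q_matrix].
#' @return A `J x 2^K` matrix `P` with `P[j, c]` the success probability of
#'   item `j` for the class with canonical index `c - 1`.
#' @export
class_success_probs <- function(model, item_params, q) {
  model <- as_model_spec(model)
  k <- ncol(q)
  patterns <- attribute_patterns(k)
  p <- matrix(NA_real_, nrow(q), nrow(patterns),
              dimnames = list(rownames(q), rownames(patterns)))
  for (j in seq_len(nrow(q))) {
    req <- which(q[j, ] == 1L)
    red_all <- patterns[, req, drop = FALSE]
    # evaluate once per distinct reduced pattern, then broadcast
    red_idx <- red_all %*% 2^((length(req) - 1):0)
    for (l in unique(as.integer(red_idx))) {
      c_idx <- which(red_idx == l)
      p[j, c_idx] <- irf_reduced(model, item_params[[j]],
                                 index_to_bits(l, length(req)))
    }
  }
  p
}

#' Count free parameters of a model on a Q-matrix
#'
#' Item parameters (DINA/DINO: 2 per item; additive: `K_j + 1` per item;
#' saturated: `2^{K_j}` per item) plus the `2^K - 1` free latent-class
#' proportions.
#'
#' @inheritParams class_success_probs
#' @return Integer count of free parameters.
#' @examples
#' q <- read_q_matrix(system.file("extdata", "pisa2012_q_matrix.csv",
#'                                package = "cdmtraj"))
#' count_parameters("GDINA", q)  # 49
#' @export
count_parameters <- function(model, q) {
  model <- as_model_spec(model)
  kj <- rowSums(q)
  item_pars <- switch(model$structure,
                      conjunctive = ,
                      disjunctive = 2L * nrow(q),
                      additive = sum(kj + 1),
                      saturated = sum(2^kj))
  as.integer(item_pars + 2^ncol(q) - 1)
}

#' Default starting parameters for estimation
#'
#' Deterministic initial values: guess = slip = 0.2 for DINA/DINO; for the
#' additive and saturated models, reduced-pattern success probabilities
#' linearly spaced from 0.2 (nothing mastered) to 0.8 (all required
#' attributes mastered), translated to the link scale with equal main
#' effects for the additive models.
#'
#' @inheritParams class_success_probs
#' @return A list of `item_params`, one per item.
#' @export
init_item_params <- function(model, q, p_null = 0.2, p_full = 0.8) {
  model <- as_model_spec(model)
  lapply(seq_len(nrow(q)), function(j) {
    kj <- sum(q[j, ])
    switch(model$structure,
      conjunctive = ,
      disjunctive = gs_params(p_null, p_null),
      additive = {
        lk <- link_fun(model$link)
        additive_params(lk(p_null), rep((lk(p_full) - lk(p_null)) / kj, kj))
      },
      saturated = {
        red <- attribute_patterns(kj)
        saturated_params(p_null + (p_full - p_null) * rowSums(red) / kj)
      })
  })
}

#' Serialize item parameters to structured text
#'
#' Writes one labelled block per item (JSON), tagged with the model name and,
#' for the saturated model, the reduced pattern each probability belongs to.
#'
#' @inheritParams class_success_probs
#' @param path Output file path.
#' @export
write_item_params <- function(model, item_params, q, path) {
  model <- as_model_spec(model)
  blocks <- lapply(seq_len(nrow(q)), function(j) {
    par <- item_params[[j]]
    req <- colnames(q)[q[j, ] == 1L]
    base <- list(item = rownames(q)[j], model = model$name,
                 required_attributes = req)
    extra <- switch(attr(par, "kind"),
      gs = list(guess = par$guess, slip = par$slip),
      additive = list(link = model$link, delta0 = par$delta0,
                      delta = stats::setNames(as.list(par$delta), req)),
      saturated = {
        red <- attribute_patterns(length(req))
        list(success_prob = stats::setNames(as.list(par$prob), rownames(red)))
      })
    c(base, extra)
  })
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
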