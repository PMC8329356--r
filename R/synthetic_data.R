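# Multi-group synthetic response data with known CDM structure, so every
# pipeline stage is testable without any external download.

# One global seed expands to fixed per-stage sub-seeds so stages can be
# regenerated independently; kept below 2^31 - 1.
sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage) %% 2147483629
}

#' Draw attribute profiles from a latent-class distribution
#'
#' @param n Number of persons (>= 1).
#' @param class_dist Probability vector over the `2^K` patterns in
#'   canonical index order.
#' @param k Number of attributes.
#' @param seed RNG seed (draws are reproducible given the seed).
#' @return An `n x k` 0/1 matrix of i.i.d. profiles; the drawn class
#'   indices are in attribute `"class_index"`.
#' @export
simulate_profiles <- function(n, class_dist, k, seed = 1) {
  if (n < 1) stop("n must be at least 1")
  check_class_dist(class_dist, k)
  restore <- local_seed(seed)
  on.exit(restore())
  idx <- sample.int(2^k, n, replace = TRUE, prob = class_dist)
  patterns <- attribute_patterns(k)
  out <- patterns[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_index") <- idx - 1L
  out
}

#' Simulate dichotomous item responses from a CDM
#'
#' Each person's score on each item is an independent Bernoulli draw with
#' the model's success probability for the person's attribute profile.
#'
#' @param profiles 0/1 matrix of attribute profiles (persons x K).
#' @param q A [q_matrix].
#' @param model A [model_spec] or name.
#' @param item_params Per-item parameter list.
#' @param seed RNG seed.
#' @param group Optional per-person group labels.
#' @return A [response_data] object (persons x items).
#' @export
simulate_responses <- function(profiles, q, model, item_params, seed = 1,
                               group = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n == 0L) {
    return(response_data(matrix(integer(0), 0L, nrow(q),
                                dimnames = list(NULL, rownames(q))),
                         group = NULL))
  }
  stopifnot(ncol(profiles) == ncol(q))
  probs <- class_success_probs(model, item_params, q)  # J x 2^K
  idx <- as.integer(profiles %*% 2^((ncol(q) - 1):0)) + 1L
  p_person <- t(probs[, idx, drop = FALSE])            # n x J
  restore <- local_seed(seed)
  on.exit(restore())
  scores <- matrix(as.integer(stats::runif(n * nrow(q)) < p_person), n,
                   dimnames = list(NULL, rownames(q)))
  response_data(scores, group = group, item_ids = rownames(q))
}

# Class distribution concentrated on a mastery chain: `chain` is a list of
# K+1 patterns from null to full, `chain_mass` the probability of each
# chain state; the remaining mass is spread uniformly over all other
# states.
chain_class_dist <- function(chain, chain_mass, k) {
  stopifnot(length(chain) == length(chain_mass), all(chain_mass >= 0),
            sum(chain_mass) <= 1 + 1e-12)
  dist <- rep(0, 2^k)
  idx <- vapply(chain, function(p) pattern_index(check_bits(p)), numeric(1L))
  stopifnot(!anyDuplicated(idx))
  dist[idx + 1L] <- chain_mass
  rest <- 1 - sum(chain_mass)
  off <- setdiff(seq_len(2^k), idx + 1L)
  dist[off] <- rest / length(off)
  dist
}

chain_from_order <- function(order, k) {
  bits <- rep(0L, k)
  chain <- list(bits)
  for (a in order) {
    bits[a] <- 1L
    chain <- c(chain, list(bits))
  }
  chain
}

#' A PISA-like multi-group scenario with planted trajectories
#'
#' Emulates the statistical structure of the PISA 2012 statistics-item
#' study at reduced size: 14 country groups (default 500 persons each)
#' answering the 9 items of the packaged Q-matrix over 4 attributes,
#' generated from an LLM (logit-link additive) model. Each group's
#' latent-class distribution is concentrated along the mastery chain
#' `(0,0,0,0) -> (1,0,0,0) -> (1,0,0,1) -> (1,0,1,1) -> (1,1,1,1)`, with
#' level masses tilted deterministically per group; two groups (`BG`,
#' `CR`) are planted with the alternative first step `(0,0,0,1)` (data
#' handling first) to exercise the secondary-trajectory logic.
#'
#' Item parameters: success probability 0.15 with nothing mastered and
#' 0.85 with every required attribute mastered, split into equal logit
#' main effects — mid-sized guessing/slipping noise typical of multiple-
#' choice assessment data.
#'
#' @param seed Global seed; per-stage sub-seeds derive from it.
#' @param n_per_group Persons per group (default 500).
#' @return A list with `responses` ([response_data], groups attached),
#'   `profiles` (true attribute profiles), `q`, `model`, `item_params`,
#'   `group_dists` (named list of true class distributions),
#'   `planted_chains` (named list of the K+1-state chains planted per
#'   group) and `config` (the scalar settings).
#' @export
pisa_like_scenario <- function(seed = 1, n_per_group = 500) {
  q <- read_q_matrix(system.file("extdata", "pisa2012_q_matrix.csv",
                                 package = "cdmtraj"))
  k <- ncol(q)
  model <- model_spec("LLM")
  item_params <- init_item_params(model, q, p_null = 0.15, p_full = 0.85)
  groups <- c("AE", "AR", "BG", "CL", "CO", "CR", "JO", "KZ", "MX", "PE",
              "RO", "RS", "TN", "UY")
  alt_groups <- c("BG", "CR")
  main_order <- c(1L, 4L, 3L, 2L)   # uncertainty, data handling, chart, average
  alt_order <- c(4L, 1L, 3L, 2L)    # data handling first
  base_mass <- c(0.40, 0.20, 0.14, 0.10, 0.09)

  group_dists <- list()
  planted_chains <- list()
  profiles <- NULL
  group_lab <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    order_g <- if (g %in% alt_groups) alt_order else main_order
    chain <- chain_from_order(order_g, k)
    # deterministic per-group tilt of the null-state mass, renormalized
    # over the rest of the chain
    tilt <- 0.30 + 0.20 * (gi - 1) / (length(groups) - 1)
    mass <- base_mass
    mass[1L] <- tilt
    mass[-1L] <- mass[-1L] * (sum(base_mass) - tilt) / sum(base_mass[-1L])
    dist <- chain_class_dist(chain, mass, k)
    group_dists[[g]] <- dist
    planted_chains[[g]] <- vapply(chain, pattern_label, character(1L))
    prof_g <- simulate_profiles(n_per_group, dist, k,
                                seed = sub_seed(seed, gi))
    profiles <- rbind(profiles, prof_g)
    group_lab <- c(group_lab, rep(g, n_per_group))
  }
  responses <- simulate_responses(profiles, q, model, item_params,
                                  seed = sub_seed(seed, 100L),
                                  group = group_lab)
  list(responses = responses, profiles = profiles, q = q, model = model,
       item_params = item_params, group_dists = group_dists,
       planted_chains = planted_chains,
       config = list(seed = seed, n_per_group = n_per_group,
                     groups = groups, alt_groups = alt_groups,
                     p_null = 0.15, p_full = 0.85,
                     base_mass = base_mass))
}
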