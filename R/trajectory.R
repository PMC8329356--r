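# Knowledge-state lattice and learning-trajectory extraction.
#
# The 2^K attribute patterns, partially ordered by mastery inclusion, form
# a Boolean lattice whose Hasse-diagram edges add exactly one attribute.
# A learning trajectory is a maximal chain from the null state to full
# mastery chosen by following the more frequent states level by level;
# runner-up states within an order of magnitude of the chosen state are
# retained as secondary branches.

# Normalize a frequency table (named vector, or data frame with columns
# `pattern` and `proportion`/`frequency`) to a numeric vector over the 2^k
# patterns in canonical order; absent patterns get 0.
as_freq_vector <- function(frequencies, k) {
  out <- stats::setNames(numeric(2^k), rownames(attribute_patterns(k)))
  if (is.null(frequencies)) return(out)
  if (is.data.frame(frequencies)) {
    valcol <- intersect(c("proportion", "frequency", "freq"),
                        colnames(frequencies))[1L]
    if (is.na(valcol) || is.null(frequencies$pattern)) {
      stop("frequency table needs `pattern` and `proportion` columns")
    }
    vals <- stats::setNames(frequencies[[valcol]],
                            as.character(frequencies$pattern))
  } else {
    vals <- frequencies
  }
  if (is.null(names(vals))) stop("pattern frequencies must be named by pattern")
  for (nm in names(vals)) {
    bits <- parse_pattern(nm)
    if (length(bits) != k) {
      stop("pattern ", sQuote(nm), " has length ", length(bits),
           " but the lattice has ", k, " attributes")
    }
    out[pattern_index(bits) + 1L] <- out[pattern_index(bits) + 1L] + vals[[nm]]
  }
  out
}

#' Build the knowledge-state lattice
#'
#' All `2^k` attribute patterns as nodes, annotated with their level
#' (number of mastered attributes) and observed group frequency, and a
#' directed edge `u -> v` whenever `v` adds exactly one attribute to `u`
#' (the prerequisite relation). The lattice has `k * 2^(k-1)` edges.
#'
#' @param k Number of attributes.
#' @param frequencies Optional pattern frequencies for one group: a named
#'   numeric vector (names are pattern tuples) or a data frame with
#'   `pattern` and `proportion` columns. Absent patterns get frequency 0.
#' @param attribute_names Optional length-`k` attribute labels.
#' @return An object of class `ks_lattice`: list with data frames `nodes`
#'   (`index`, `pattern`, `level`, `freq`) and `edges` (`from`, `to`,
#'   `attribute`, `attribute_name`), plus `k` and `attribute_names`.
#' @export
build_lattice <- function(k, frequencies = NULL, attribute_names = NULL) {
  stopifnot(k >= 1)
  if (is.null(attribute_names)) attribute_names <- paste0("A", seq_len(k))
  stopifnot(length(attribute_names) == k)
  patterns <- attribute_patterns(k)
  freq <- as_freq_vector(frequencies, k)
  nodes <- data.frame(index = 0:(2^k - 1), pattern = rownames(patterns),
                      level = rowSums(patterns), freq = unname(freq),
                      stringsAsFactors = FALSE)
  from <- character(0); to <- character(0); attribute <- integer(0)
  for (c_ in seq_len(nrow(patterns))) {
    bits <- patterns[c_, ]
    for (a in which(bits == 0L)) {
      v <- bits; v[a] <- 1L
      from <- c(from, rownames(patterns)[c_])
      to <- c(to, pattern_label(v))
      attribute <- c(attribute, a)
    }
  }
  edges <- data.frame(from = from, to = to, attribute = attribute,
                      attribute_name = attribute_names[attribute],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = k,
                 attribute_names = attribute_names),
            class = "ks_lattice")
}

#' @export
print.ks_lattice <- function(x, ...) {
  cat(sprintf("<ks_lattice> K = %d: %d states, %d prerequisite edges\n",
              x$k, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract the learning trajectory from a lattice
#'
#' Walks the lattice from the null state to full mastery. At each level the
#' successor (current state plus one attribute) with the highest observed
#' frequency is chosen, ties broken by the lowest added-attribute index.
#' The runner-up successor is recorded; it is kept as a secondary branch
#' when the chosen-to-runner-up frequency ratio is at most
#' `secondary_ratio` (default 10: a runner-up more than an order of
#' magnitude rarer is not considered a trajectory). A retained secondary
#' branch is extended greedily one level forward. If every successor at
#' some level has frequency 0 the step is resolved by the tie-break and
#' flagged unsupported.
#'
#' @param lattice A [build_lattice] result with frequencies.
#' @param secondary_ratio Largest main/runner-up ratio that still counts as
#'   a secondary trajectory (default 10; a ratio of exactly 10 is kept).
#' @param restrict_top_k Treat frequencies outside the group's `top_k` most
#'   frequent patterns as 0 (default `NULL`: use all), mirroring analyses
#'   run from printed top-five tables.
#' @param scorer `"greedy"` (default, level-by-level) or `"global"`
#'   (maximize the product of state frequencies over all `k!` complete
#'   chains; provided for sensitivity analysis).
#' @return An object of class `trajectory`: list with `main` (character
#'   vector of `k + 1` pattern labels), `steps` (per-level provenance:
#'   chosen state and frequency, runner-up and its frequency, ratio,
#'   whether a secondary branch was kept, whether the step was
#'   unsupported), `secondary` (data frame of retained branches with their
#'   one-step greedy extension), `k`, `freq`, `scorer`.
#' @export
extract_trajectory <- function(lattice, secondary_ratio = 10,
                               restrict_top_k = NULL,
                               scorer = c("greedy", "global")) {
  scorer <- match.arg(scorer)
  k <- lattice$k
  patterns <- attribute_patterns(k)
  freq <- stats::setNames(lattice$nodes$freq, lattice$nodes$pattern)
  if (!is.null(restrict_top_k) && restrict_top_k < length(freq)) {
    ord <- order(-freq, lattice$nodes$index)
    keep <- ord[seq_len(restrict_top_k)]
    freq[-keep] <- 0
  }

  successors <- function(bits) {
    lapply(which(bits == 0L), function(a) {
      v <- bits; v[a] <- 1L
      list(bits = v, attribute = a, label = pattern_label(v),
           freq = unname(freq[pattern_label(v)]))
    })
  }
  best_of <- function(succ) {
    f <- vapply(succ, `[[`, numeric(1L), "freq")
    a <- vapply(succ, `[[`, integer(1L), "attribute")
    ord <- order(-f, a)
    list(best = succ[[ord[1L]]],
         runner = if (length(ord) > 1L) succ[[ord[2L]]] else NULL)
  }

  main_bits <- if (scorer == "global") {
    global_chain(freq, k)
  } else NULL

  bits <- rep(0L, k)
  main <- pattern_label(bits)
  steps <- NULL
  secondary <- NULL
  for (level in seq_len(k)) {
    succ <- successors(bits)
    pick <- best_of(succ)
    chosen <- pick$best
    if (!is.null(main_bits)) {
      # global scorer dictates the chain; provenance still reports the
      # greedy runner-up among the remaining successors
      target <- main_bits[[level + 1L]]
      chosen <- succ[[which(vapply(succ, function(s)
        identical(s$bits, target), logical(1L)))]]
      others <- succ[!vapply(succ, function(s) identical(s$bits, target),
                             logical(1L))]
      pick$runner <- if (length(others)) best_of(others)$best else NULL
    } else if (!is.null(pick$runner) &&
               identical(pick$runner$label, chosen$label)) {
      pick$runner <- NULL
    }
    runner <- pick$runner
    ratio <- if (!is.null(runner) && runner$freq > 0) {
      chosen$freq / runner$freq
    } else NA_real_
    keep_secondary <- !is.na(ratio) && ratio <= secondary_ratio
    unsupported <- chosen$freq == 0
    steps <- rbind(steps, data.frame(
      level = level, from = pattern_label(bits), state = chosen$label,
      attribute = chosen$attribute, freq = chosen$freq,
      runner_up = if (is.null(runner)) NA_character_ else runner$label,
      runner_freq = if (is.null(runner)) NA_real_ else runner$freq,
      ratio = ratio, secondary = keep_secondary, unsupported = unsupported,
      stringsAsFactors = FALSE))
    if (keep_secondary) {
      ext <- NA_character_
      if (level < k) {
        ext <- best_of(successors(runner$bits))$best$label
      }
      secondary <- rbind(secondary, data.frame(
        level = level, from = pattern_label(bits), state = runner$label,
        freq = runner$freq, ratio = ratio, next_state = ext,
        stringsAsFactors = FALSE))
    }
    bits <- chosen$bits
    main <- c(main, chosen$label)
  }
  structure(list(main = main, steps = steps, secondary = secondary,
                 k = k, freq = freq, scorer = scorer,
                 attribute_names = lattice$attribute_names),
            class = "trajectory")
}

# Best chain under the global product-of-frequencies score over all k!
# attribute orders; ties broken by the lexicographically smallest
# attribute-order sequence.
global_chain <- function(freq, k) {
  perms <- permutations(k)
  best <- NULL; best_score <- -Inf; best_order <- NULL
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    bits <- rep(0L, k)
    chain <- list(bits)
    score <- 0
    for (a in ord) {
      bits[a] <- 1L
      chain <- c(chain, list(bits))
      score <- score + log(max(freq[pattern_label(bits)], 1e-300))
    }
    better <- score > best_score ||
      (score == best_score && !is.null(best_order) &&
         lexico_less(ord, best_order))
    if (better) {
      best <- chain; best_score <- score; best_order <- ord
    }
  }
  best
}

lexico_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- NULL
  for (a in seq_len(k)) {
    rest <- setdiff(seq_len(k), a)
    out <- rbind(out, cbind(a, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> main: ", paste(x$main, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$secondary) && nrow(x$secondary) > 0L) {
    for (i in seq_len(nrow(x$secondary))) {
      cat(sprintf("  secondary at level %d: %s (ratio %.2f)\n",
                  x$secondary$level[i], x$secondary$state[i],
                  x$secondary$ratio[i]))
    }
  }
  invisible(x)
}

#' Extract trajectories for every group of a frequency table
#'
#' Convenience wrapper looping [extract_trajectory] over the groups of a
#' [pattern_frequencies] table; groups with an empty frequency table are
#' excluded with a warning.
#'
#' @param freq_table A [pattern_frequencies] data frame (columns `group`,
#'   `pattern`, `proportion`).
#' @param attribute_names Optional attribute labels.
#' @param ... Passed to [extract_trajectory].
#' @return A named list of [extract_trajectory] results.
#' @export
group_trajectories <- function(freq_table, attribute_names = NULL, ...) {
  k <- attr(freq_table, "k")
  if (is.null(k)) {
    k <- length(parse_pattern(freq_table$pattern[
      which(!is.na(freq_table$pattern))[1L]]))
  }
  out <- list()
  for (g in unique(freq_table$group)) {
    sub <- freq_table[freq_table$group == g, , drop = FALSE]
    if (nrow(sub) == 0L || all(is.na(sub$proportion)) ||
        sum(sub$proportion, na.rm = TRUE) == 0) {
      warning("group ", sQuote(g), " has an empty frequency table; excluded")
      next
    }
    lat <- build_lattice(k, sub, attribute_names = attribute_names)
    out[[g]] <- extract_trajectory(lat, ...)
  }
  out
}

#' Compare learning trajectories across groups
#'
#' Clusters groups by identical main chains and tallies, per level, which
#' attribute the groups add at that step.
#'
#' @param trajectories Named list of [extract_trajectory] results over the
#'   same attribute set (e.g. from [group_trajectories]).
#' @return A list with `summary` (one row per group: the main chain and the
#'   attribute added at each level), `clusters` (one row per distinct
#'   chain: its groups and size) and `step_counts` (levels-by-attributes
#'   count matrix of which attribute each group adds at each step).
#' @export
compare_trajectories <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  k <- trajectories[[1L]]$k
  for (tr in trajectories) stopifnot(tr$k == k)
  attr_names <- trajectories[[1L]]$attribute_names
  groups <- names(trajectories)
  if (is.null(groups)) groups <- paste0("group", seq_along(trajectories))
  chain_str <- vapply(trajectories, function(tr)
    paste(tr$main, collapse = " -> "), character(1L))
  step_attr <- t(vapply(trajectories, function(tr) tr$steps$attribute,
                        integer(k)))
  summary <- data.frame(group = groups, chain = unname(chain_str),
                        stringsAsFactors = FALSE)
  for (l in seq_len(k)) {
    summary[[paste0("step", l, "_attribute")]] <- attr_names[step_attr[, l]]
  }
  chains <- unique(chain_str)
  clusters <- data.frame(
    chain = chains,
    groups = vapply(chains, function(ch)
      paste(groups[chain_str == ch], collapse = ", "), character(1L)),
    size = vapply(chains, function(ch) sum(chain_str == ch), numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  step_counts <- matrix(0L, k, k,
                        dimnames = list(paste0("level", seq_len(k)),
                                        attr_names))
  for (l in seq_len(k)) {
    tab <- table(factor(step_attr[, l], levels = seq_len(k)))
    step_counts[l, ] <- as.integer(tab)
  }
  list(summary = summary, clusters = clusters, step_counts = step_counts)
}

#' Export a lattice or trajectory as DOT or JSON
#'
#' DOT (Graphviz dialect) draws every knowledge state, ranked by level; for
#' a trajectory the main chain is drawn as solid red bold edges and the
#' retained secondary branches as dashed black edges, with all other
#' prerequisite edges light gray. JSON serializes the object so that
#' [trajectory_from_json] can reconstruct it.
#'
#' @param x A `ks_lattice` or `trajectory`.
#' @param format `"DOT"` or `"JSON"`.
#' @param path Optional output file.
#' @return The document as a character scalar (invisibly when `path` is
#'   given).
#' @export
export_graph <- function(x, format = c("DOT", "JSON"), path = NULL) {
  format <- match.arg(toupper(format[1L]), c("DOT", "JSON"))
  doc <- if (inherits(x, "ks_lattice")) {
    if (format == "DOT") lattice_dot(x) else
      as.character(jsonlite::toJSON(list(kind = "ks_lattice", k = x$k,
                                         attribute_names = x$attribute_names,
                                         nodes = x$nodes, edges = x$edges),
                                    dataframe = "rows", auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE))
  } else if (inherits(x, "trajectory")) {
    if (format == "DOT") trajectory_dot(x) else
      as.character(jsonlite::toJSON(list(kind = "trajectory", k = x$k,
                                         scorer = x$scorer,
                                         attribute_names = x$attribute_names,
                                         main = x$main, steps = x$steps,
                                         secondary = x$secondary,
                                         freq = as.list(x$freq)),
                                    dataframe = "rows", auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE))
  } else {
    stop("export_graph handles ks_lattice and trajectory objects")
  }
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

dot_id <- function(label) gsub("[^01]", "", label)

lattice_dot <- function(x) {
  lines <- c("digraph knowledge_states {", "  rankdir=BT;",
             "  node [shape=box];")
  for (i in seq_len(nrow(x$nodes))) {
    lines <- c(lines, sprintf("  s%s [label=\"%s\"];",
                              dot_id(x$nodes$pattern[i]), x$nodes$pattern[i]))
  }
  for (i in seq_len(nrow(x$edges))) {
    lines <- c(lines, sprintf("  s%s -> s%s;", dot_id(x$edges$from[i]),
                              dot_id(x$edges$to[i])))
  }
  paste(c(lines, "}"), collapse = "\n")
}

trajectory_dot <- function(x) {
  lat <- build_lattice(x$k, x$freq, attribute_names = x$attribute_names)
  main_edges <- paste(x$main[-length(x$main)], x$main[-1L], sep = "|")
  sec_edges <- character(0)
  if (!is.null(x$secondary) && nrow(x$secondary) > 0L) {
    sec_edges <- paste(x$secondary$from, x$secondary$state, sep = "|")
    ext <- !is.na(x$secondary$next_state)
    sec_edges <- c(sec_edges, paste(x$secondary$state[ext],
                                    x$secondary$next_state[ext], sep = "|"))
  }
  lines <- c("digraph learning_trajectory {", "  rankdir=BT;",
             "  node [shape=box];")
  on_path <- unique(c(x$main, if (!is.null(x$secondary)) x$secondary$state,
                      if (!is.null(x$secondary)) x$secondary$next_state))
  for (i in seq_len(nrow(lat$nodes))) {
    pat <- lat$nodes$pattern[i]
    style <- if (pat %in% x$main) " style=bold color=red" else
      if (pat %in% on_path) " style=dashed" else " color=gray"
    lines <- c(lines, sprintf("  s%s [label=\"%s (%.3f)\"%s];",
                              dot_id(pat), pat, lat$nodes$freq[i], style))
  }
  for (i in seq_len(nrow(lat$edges))) {
    key <- paste(lat$edges$from[i], lat$edges$to[i], sep = "|")
    attrs <- if (key %in% main_edges) {
      " [color=\"red\" style=\"solid\" penwidth=2]"
    } else if (key %in% sec_edges) {
      " [color=\"black\" style=\"dashed\"]"
    } else {
      " [color=\"gray85\"]"
    }
    lines <- c(lines, sprintf("  s%s -> s%s%s;", dot_id(lat$edges$from[i]),
                              dot_id(lat$edges$to[i]), attrs))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @rdname export_graph
#' @param json A JSON document produced by `export_graph(..., "JSON")` for
#'   a trajectory.
#' @export
trajectory_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  if (!identical(obj$kind, "trajectory")) {
    stop("not a serialized trajectory")
  }
  secondary <- obj$secondary
  if (!is.null(secondary) && nrow(as.data.frame(secondary)) == 0L) {
    secondary <- NULL
  }
  structure(list(main = as.character(obj$main),
                 steps = as.data.frame(obj$steps),
                 secondary = if (is.null(secondary)) NULL else
                   as.data.frame(secondary),
                 k = obj$k, freq = unlist(obj$freq), scorer = obj$scorer,
                 attribute_names = as.character(obj$attribute_names)),
            class = "trajectory")
}
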