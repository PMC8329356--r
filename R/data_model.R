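#' Construct a Q-matrix
#'
#' A Q-matrix records, for each item of a test, which latent attributes the
#' item requires: `q[j, k] = 1` means item `j` cannot be solved without
#' attribute `k` contributing. Rows are items, columns attributes; both
#' orders are meaningful and preserved throughout the package.
#'
#' @param x A matrix or data frame of 0/1 entries, items in rows.
#' @param item_ids,attribute_names Optional character vectors overriding the
#'   dimnames of `x`.
#' @return An object of class `q_matrix`: an integer matrix with item row
#'   names and attribute column names.
#' @details Validation enforces that every entry is 0 or 1 and that every
#'   item requires at least one attribute (an item measuring nothing is
#'   invalid); an attribute required by no item cannot be diagnosed and is
#'   flagged with a warning.
#' @examples
#' q <- q_matrix(rbind(c(1, 1, 1, 0), c(0, 1, 0, 1)))
#' n_attributes(q)
#' @export
q_matrix <- function(x, item_ids = NULL, attribute_names = NULL) {
  m <- as.matrix(x)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "integer")
  }
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    stop("Q-matrix entries must all be 0 or 1")
  }
  storage.mode(m) <- "integer"
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("a Q-matrix needs at least one item and one attribute")
  }
  if (is.null(item_ids)) {
    item_ids <- rownames(m)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(m)))
  }
  if (is.null(attribute_names)) {
    attribute_names <- colnames(m)
    if (is.null(attribute_names)) attribute_names <- paste0("A", seq_len(ncol(m)))
  }
  dimnames(m) <- list(item_ids, attribute_names)
  zero_items <- rowSums(m) == 0L
  if (any(zero_items)) {
    stop("item(s) requiring no attribute: ",
         paste(item_ids[zero_items], collapse = ", "))
  }
  zero_attrs <- colSums(m) == 0L
  if (any(zero_attrs)) {
    warning("attribute(s) required by no item (not measurable): ",
            paste(attribute_names[zero_attrs], collapse = ", "))
  }
  structure(m, class = c("q_matrix", "matrix", "array"))
}

#' @rdname q_matrix
#' @param q A `q_matrix`.
#' @export
n_attributes <- function(q) ncol(q)

#' @rdname q_matrix
#' @export
n_items <- function(q) nrow(q)

#' Read / write a Q-matrix CSV
#'
#' The file dialect is comma-separated with a header row: first column item
#' id, remaining columns one per attribute (header gives attribute names).
#'
#' @param path Path to a CSV file.
#' @return `read_q_matrix()` returns a validated [q_matrix]; `write_q_matrix()`
#'   returns `path` invisibly.
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Q-matrix file needs an item column plus attribute columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(m %in% c(0, 1))) {
    stop("non-binary entry in Q-matrix file ", sQuote(path))
  }
  q_matrix(m, item_ids = ids, attribute_names = colnames(df)[-1L])
}

#' @rdname read_q_matrix
#' @param q A `q_matrix`.
#' @export
write_q_matrix <- function(q, path) {
  df <- data.frame(item = rownames(q), unclass(q), check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct dichotomous response data
#'
#' Holds a persons-by-items 0/1 score matrix (NA = missing), an optional
#' per-person group label (e.g. a country code), and the item order that
#' must match the Q-matrix used for fitting.
#'
#' @param scores Matrix or data frame of 0/1/NA scores, persons in rows.
#' @param group Optional per-person labels (length = number of persons).
#' @param person_ids,item_ids Optional id vectors; default to dimnames or
#'   generated ids.
#' @return An object of class `response_data`: a list with elements
#'   `scores` (integer matrix), `group` (character or NULL), `person_ids`,
#'   `item_ids`.
#' @export
response_data <- function(scores, group = NULL, person_ids = NULL,
                          item_ids = NULL) {
  m <- as.matrix(scores)
  ok <- is.na(m) | m == 0 | m == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid score %s at person row %d, item column %d (must be 0, 1 or missing)",
                 format(m[bad[1L], bad[2L]]), bad[1L], bad[2L]))
  }
  storage.mode(m) <- "integer"
  if (is.null(person_ids)) {
    person_ids <- rownames(m)
    if (is.null(person_ids)) {
      person_ids <- sprintf("p%d", seq_len(nrow(m)))
    }
  }
  if (is.null(item_ids)) {
    item_ids <- colnames(m)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(m)))
  }
  dimnames(m) <- list(person_ids, item_ids)
  if (!is.null(group)) {
    if (length(group) != nrow(m)) {
      stop("group labels must match the number of persons")
    }
    group <- as.character(group)
  }
  structure(list(scores = m, group = group,
                 person_ids = as.character(person_ids),
                 item_ids = as.character(item_ids)),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("<response_data> %d persons x %d items", nrow(x$scores),
              ncol(x$scores)))
  if (!is.null(x$group)) {
    cat(sprintf(", %d group(s)", length(unique(x$group))))
  }
  miss <- mean(is.na(x$scores))
  cat(sprintf(", %.1f%% missing\n", 100 * miss))
  invisible(x)
}

#' Read / write response data CSV
#'
#' Dialect: first column person id, optional second column `group`,
#' remaining columns item scores in 0/1 with a configurable missing marker.
#' `read_responses()` reports per-item missing rates via `message()` when
#' any score is missing.
#'
#' @param path CSV path.
#' @param missing_marker Token standing for a missing score (default "NA").
#' @param group_column Name of the group column if present (default
#'   `"group"`; set `NULL` to force treating every non-id column as an item).
#' @return A [response_data] object.
#' @export
read_responses <- function(path, missing_marker = "NA", group_column = "group") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character())
  if (ncol(df) < 2L) stop("response file needs a person id column plus item columns")
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  group <- NULL
  if (!is.null(group_column) && group_column %in% colnames(df)) {
    group <- df[[group_column]]
    df <- df[, setdiff(colnames(df), group_column), drop = FALSE]
  }
  m <- as.matrix(df)
  m[m == missing_marker] <- NA
  bad <- !is.na(m) & !(m %in% c("0", "1"))
  if (any(bad)) {
    loc <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid score %s at row %d, column %s in %s",
                 sQuote(m[loc[1L], loc[2L]]), loc[1L],
                 sQuote(colnames(m)[loc[2L]]), sQuote(path)))
  }
  storage.mode(m) <- "integer"
  if (anyNA(m)) {
    rates <- colMeans(is.na(m))
    message("per-item missing rates: ",
            paste(sprintf("%s=%.3f", colnames(m), rates), collapse = ", "))
  }
  response_data(m, group = group, person_ids = ids, item_ids = colnames(m))
}

#' @rdname read_responses
#' @param responses A [response_data] object.
#' @export
write_responses <- function(responses, path, missing_marker = "NA") {
  m <- responses$scores
  ch <- matrix(as.character(m), nrow(m), dimnames = dimnames(m))
  ch[is.na(ch)] <- missing_marker
  df <- data.frame(person = responses$person_ids, check.names = FALSE,
                   row.names = NULL)
  if (!is.null(responses$group)) df$group <- responses$group
  df <- cbind(df, as.data.frame(ch, check.names = FALSE, row.names = NULL))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number-correct score distribution
#'
#' Tabulates the number of correct answers per person (0..J), with percents
#' and cumulative percents rounded to one decimal, the convention used in
#' PISA-style descriptive tables.
#'
#' @param responses A [response_data] object.
#' @param missing How to treat missing scores: `"error"` (default) or
#'   `"incorrect"` (count as 0).
#' @return A data frame of class `score_distribution` with columns `score`,
#'   `frequency`, `percent`, `cum_percent`, plus attribute `total`.
#' @export
score_distribution <- function(responses, missing = c("error", "incorrect")) {
  missing <- match.arg(missing)
  m <- responses$scores
  if (nrow(m) == 0L) stop("empty response data")
  if (anyNA(m)) {
    if (missing == "error") {
      stop("response data contain missing scores; use missing = \"incorrect\" to score them 0")
    }
    m[is.na(m)] <- 0L
  }
  j <- ncol(m)
  t_i <- rowSums(m)
  freq <- vapply(0:j, function(t) sum(t_i == t), integer(1L))
  total <- nrow(m)
  out <- data.frame(
    score = 0:j,
    frequency = freq,
    percent = round(100 * freq / total, 1L),
    cum_percent = round(100 * cumsum(freq) / total, 1L)
  )
  attr(out, "total") <- total
  class(out) <- c("score_distribution", "data.frame")
  out
}
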