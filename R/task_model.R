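#' @title Visual memory task model
#' @description Representation of the 6-column by 4-row picture-array
#'   recognition task and its three memory measures: total recall,
#'   semantic clustering and visual scanning.
#' @name task_model
NULL

#' The four semantic categories of the task
#' @return Character vector of the category names.
#' @export
task_categories <- function() c("animals", "tools", "food", "clothing")

#' Build a stimulus array
#'
#' Places 24 categorized items (6 per category) on a 4-row by 6-column
#' grid.  In the `organized` condition every row holds a single category
#' (the external organization cue); in the `randomized` condition the 24
#' positions are a seeded uniform permutation.  Twelve items (3 per
#' category) are flagged as targets; the remaining twelve act as
#' distracters on the recognition sheet.
#'
#' @param items Named list mapping each category name to 6 item labels,
#'   or a character vector of 24 labels taken 6 per category in
#'   [task_categories()] order.
#' @param condition `"randomized"` or `"organized"`.
#' @param targets Character vector of 12 target labels (3 per category),
#'   or `NULL` to pick the first 3 of each category.
#' @param seed Integer seed controlling the randomized placement.
#' @return A `stimulus_array`: list with `items` (data frame of
#'   `item`, `category`, `row`, `col`, `is_target`; rows/cols 0-based)
#'   and `condition`.
#' @export
#' @examples
#' arr <- build_array(condition = "organized")
#' table(arr$items$category[arr$items$is_target])
build_array <- function(items = NULL,
                        condition = c("randomized", "organized"),
                        targets = NULL, seed = 0L) {
  condition <- match.arg(condition)
  cats <- task_categories()
  if (is.null(items)) {
    items <- stats::setNames(
      lapply(cats, function(cc) paste0(substr(cc, 1, 3), 1:6)), cats)
  }
  if (is.character(items)) {
    if (length(items) != 24L) stop("need 24 item labels")
    items <- stats::setNames(split(items, rep(cats, each = 6)), cats)
  }
  if (!setequal(names(items), cats) ||
      any(vapply(items, length, 1L) != 6L) ||
      anyDuplicated(unlist(items)))
    stop("items must be 24 distinct labels, 6 per category")
  if (is.null(targets)) targets <- unlist(lapply(items, `[`, 1:3))
  tc <- vapply(cats, function(cc) sum(targets %in% items[[cc]]), 1L)
  if (length(targets) != 12L || any(tc != 3L) || anyDuplicated(targets))
    stop("targets must be 12 distinct labels, 3 per category")

  df <- data.frame(item = unlist(items, use.names = FALSE),
                   category = rep(cats, each = 6),
                   stringsAsFactors = FALSE)
  if (condition == "organized") {
    # one category per row, left-to-right within the row
    df$row <- rep(0:3, each = 6)
    df$col <- rep(0:5, times = 4)
  } else {
    perm <- local({
      old <- get_rng_state()
      on.exit(set_rng_state(old))
      set.seed(as.integer(seed))
      sample.int(24L)
    })
    df$row <- (perm - 1L) %/% 6L
    df$col <- (perm - 1L) %% 6L
  }
  df$is_target <- df$item %in% targets
  structure(list(items = df, condition = condition), class = "stimulus_array")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.stimulus_array <- function(x, ...) {
  cat("stimulus array (", x$condition, " condition)\n", sep = "")
  g <- matrix("", 4, 6)
  g[cbind(x$items$row + 1, x$items$col + 1)] <-
    ifelse(x$items$is_target, toupper(x$items$item), x$items$item)
  print(g, quote = FALSE)
  invisible(x)
}

#' Record an ordered recognition response
#'
#' Wraps the sequence of circled items from the recognition sheet.
#' Entries may be targets or distracters (intrusions); duplicates are
#' rejected rather than deduplicated, because a double circling is a
#' recording error, not a response.
#'
#' @param sequence Character vector of circled item labels in order.
#' @param array The studied [build_array()] object.
#' @param distracters Labels of the 12 distracter drawings on the
#'   recognition sheet; defaults to `"dis1" ... "dis12"`.
#' @return A `recall_record` object.
#' @export
recall_record <- function(sequence, array,
                          distracters = paste0("dis", 1:12)) {
  stopifnot(inherits(array, "stimulus_array"))
  if (anyDuplicated(sequence)) stop("duplicate circlings in response sequence")
  tg <- array$items$item[array$items$is_target]
  unknown <- setdiff(sequence, c(tg, distracters))
  if (length(unknown))
    stop("unknown response item(s): ", paste(unknown, collapse = ", "))
  structure(list(sequence = as.character(sequence), array = array,
                 distracters = distracters), class = "recall_record")
}

# ordered subsequence of correctly identified targets
target_subsequence <- function(record) {
  tg <- record$array$items$item[record$array$items$is_target]
  record$sequence[record$sequence %in% tg]
}

item_category <- function(array, items) {
  array$items$category[match(items, array$items$item)]
}
item_rowcol <- function(array, items) {
  i <- match(items, array$items$item)
  cbind(row = array$items$row[i], col = array$items$col[i])
}

#' Total recall score
#'
#' One point per correctly identified target; distracter circlings score
#' nothing.  Maximum 12.
#'
#' @param record A [recall_record()].
#' @return Integer in 0..12.
#' @export
score_total_recall <- function(record) {
  stopifnot(inherits(record, "recall_record"))
  length(target_subsequence(record))
}

#' Semantic clustering score
#'
#' Counts consecutive pairs of correctly identified targets that share a
#' semantic category, indexing a categorization retrieval strategy.
#' Maximum 8 (4 categories x (3 - 1) within-category transitions).
#'
#' @param record A [recall_record()].
#' @param drop_distracters If `TRUE` (default) the score is computed on
#'   the distracter-free subsequence, so a circled distracter does not
#'   break a cluster; if `FALSE` a distracter interrupts adjacency.
#' @return Integer in 0..8.
#' @export
score_semantic_clustering <- function(record, drop_distracters = TRUE) {
  stopifnot(inherits(record, "recall_record"))
  seqn <- if (drop_distracters) target_subsequence(record) else record$sequence
  tg <- record$array$items$item[record$array$items$is_target]
  if (length(seqn) < 2) return(0L)
  score <- 0L
  for (i in seq_len(length(seqn) - 1L)) {
    a <- seqn[i]; b <- seqn[i + 1L]
    if (a %in% tg && b %in% tg &&
        item_category(record$array, a) == item_category(record$array, b))
      score <- score + 1L
  }
  score
}

#' Visual scanning score
#'
#' Counts consecutive pairs of correctly identified targets whose
#' positions in the learning array are horizontally or vertically
#' adjacent (4-neighbourhood; diagonals do not count), indexing a
#' systematic spatial scanning strategy.  Maximum 11.
#'
#' @inheritParams score_semantic_clustering
#' @return Integer in 0..11.
#' @export
score_visual_scanning <- function(record, drop_distracters = TRUE) {
  stopifnot(inherits(record, "recall_record"))
  seqn <- if (drop_distracters) target_subsequence(record) else record$sequence
  tg <- record$array$items$item[record$array$items$is_target]
  if (length(seqn) < 2) return(0L)
  score <- 0L
  for (i in seq_len(length(seqn) - 1L)) {
    a <- seqn[i]; b <- seqn[i + 1L]
    if (!(a %in% tg && b %in% tg)) next
    pa <- item_rowcol(record$array, a)
    pb <- item_rowcol(record$array, b)
    if (anyNA(pa) || anyNA(pb)) stop("target lacks an array position")
    if (abs(pa[1, "row"] - pb[1, "row"]) + abs(pa[1, "col"] - pb[1, "col"]) == 1L)
      score <- score + 1L
  }
  score
}

#' Score all three memory measures
#'
#' @inheritParams score_semantic_clustering
#' @return Data frame with `total_recall`, `semantic_clustering`,
#'   `visual_scanning`.
#' @export
score_recall <- function(record, drop_distracters = TRUE) {
  data.frame(
    total_recall = score_total_recall(record),
    semantic_clustering = score_semantic_clustering(record, drop_distracters),
    visual_scanning = score_visual_scanning(record, drop_distracters))
}

#' Maximum attainable scores for an array
#'
#' Exhaustive maxima over recall orders of the 12 targets: total recall
#' is always 12 and semantic clustering always 8; the visual scanning
#' maximum is the longest path through the 12 target positions in the
#' grid 4-adjacency graph (at most 11), found by depth-first search.
#'
#' @param array A [build_array()] object.
#' @return Named numeric vector `max_recall`, `max_clustering`,
#'   `max_scanning`.
#' @export
brute_force_max_scores <- function(array) {
  stopifnot(inherits(array, "stimulus_array"))
  t_idx <- which(array$items$is_target)
  pos <- cbind(array$items$row[t_idx], array$items$col[t_idx])
  n <- length(t_idx)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    abs(pos[i, 1] - pos[j, 1]) + abs(pos[i, 2] - pos[j, 2]) == 1L))
  best <- 0L
  dfs <- function(v, visited, len) {
    if (len > best) best <<- len
    for (w in which(adj[v, ] & !visited)) {
      visited[w] <- TRUE
      dfs(w, visited, len + 1L)
      visited[w] <- FALSE
    }
  }
  for (v in seq_len(n)) {
    visited <- rep(FALSE, n); visited[v] <- TRUE
    dfs(v, visited, 0L)
  }
  c(max_recall = n, max_clustering = 8L, max_scanning = best)
}

#' Read / write stimulus arrays and responses as CSV
#'
#' `write_array_csv()` stores the item table (item, category, row, col,
#' is_target); `read_array_csv()` rebuilds a `stimulus_array`;
#' `read_responses_csv()` reads a long table (`subject`, `order`,
#' `item`) into a named list of response sequences.
#'
#' @param array A `stimulus_array`.
#' @param path File path.
#' @param condition Condition label recorded on read (not stored in CSV).
#' @return `read_array_csv` returns a `stimulus_array`;
#'   `read_responses_csv` a named list of character vectors.
#' @export
write_array_csv <- function(array, path) {
  utils::write.csv(array$items, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_array_csv
#' @export
read_array_csv <- function(path, condition = "randomized") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "category", "row", "col", "is_target")
  if (!all(need %in% names(df))) stop("array CSV missing columns")
  df$is_target <- as.logical(df$is_target)
  structure(list(items = df[need], condition = condition),
            class = "stimulus_array")
}

#' @rdname write_array_csv
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "order", "item") %in% names(df)))
    stop("responses CSV needs subject, order, item columns")
  df <- df[order(df$subject, df$order), ]
  split(df$item, df$subject)
}
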