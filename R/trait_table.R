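#' Plant-by-trait phenotype table
#'
#' A `trait_table` couples a numeric plants x traits value matrix (missing
#' values allowed) with per-plant labels: a plant identifier, the variety the
#' plant belongs to, and a group label (e.g. a spring/winter crop-type split).
#'
#' @param values data.frame of numeric trait columns (one row per plant).
#' @param plant_id character vector of unique plant identifiers.
#' @param variety character vector of variety labels (one per plant).
#' @param group character vector of group labels; a single value is recycled.
#' @return An object of class `trait_table` with elements `values`,
#'   `plant_id`, `variety`, `group` and `trait_names`.
#' @examples
#' tt <- trait_table(data.frame(a = rnorm(4), b = rnorm(4)),
#'                   plant_id = paste0("p", 1:4),
#'                   variety = c("v1", "v1", "v2", "v2"))
#' trait_values(tt)
#' @export
trait_table <- function(values, plant_id = NULL, variety, group = "all") {
  values <- as.data.frame(values)
  if (!all(vapply(values, is.numeric, logical(1L)))) {
    stop("all trait columns must be numeric")
  }
  if (anyDuplicated(names(values))) stop("trait names must be unique")
  n <- nrow(values)
  if (is.null(plant_id)) plant_id <- sprintf("plant_%04d", seq_len(n))
  plant_id <- as.character(plant_id)
  variety <- as.character(variety)
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, n)
  if (length(plant_id) != n || length(variety) != n || length(group) != n) {
    stop("label lengths must match the number of rows")
  }
  if (any(is.na(variety)) || any(variety == "")) stop("every row needs a variety label")
  structure(list(values = values, plant_id = plant_id, variety = variety,
                 group = group, trait_names = names(values)),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$values), "plants x", ncol(x$values), "traits;",
      length(unique(x$variety)), "varieties;",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' Extract the numeric trait matrix of a trait table
#'
#' @param table a [trait_table()].
#' @param traits optional subset of trait names.
#' @return Numeric matrix (plants x traits).
#' @export
trait_values <- function(table, traits = NULL) {
  stopifnot(inherits(table, "trait_table"))
  m <- as.matrix(table$values)
  if (!is.null(traits)) {
    missing <- setdiff(traits, colnames(m))
    if (length(missing)) stop("unknown traits: ", paste(missing, collapse = ", "))
    m <- m[, traits, drop = FALSE]
  }
  m
}

#' Subset the rows of a trait table
#'
#' @param table a [trait_table()].
#' @param i integer or logical row index.
#' @return A [trait_table()] with the selected plants.
#' @export
trait_table_subset <- function(table, i) {
  trait_table(table$values[i, , drop = FALSE], table$plant_id[i],
              table$variety[i], table$group[i])
}

#' Replace trait columns, keeping labels
#' @noRd
trait_table_replace <- function(table, values) {
  trait_table(as.data.frame(values), table$plant_id, table$variety, table$group)
}

#' Read and write trait tables as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a header row; columns are
#' `plant_id`, `variety`, `group`, then one column per trait. Empty cells
#' denote missing values.
#'
#' @param table a [trait_table()].
#' @param path file path.
#' @return `read_trait_table` returns a `trait_table`; `write_trait_table`
#'   returns `path` invisibly.
#' @export
write_trait_table <- function(table, path) {
  df <- cbind(data.frame(plant_id = table$plant_id, variety = table$variety,
                         group = table$group, stringsAsFactors = FALSE),
              table$values)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = "")
  need <- c("plant_id", "variety", "group")
  if (!all(need %in% names(df))) {
    stop("trait table CSV must have columns: ", paste(need, collapse = ", "))
  }
  vals <- df[, setdiff(names(df), need), drop = FALSE]
  trait_table(vals, df$plant_id, df$variety, df$group)
}
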