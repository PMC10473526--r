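#' Per-trait normalising transform specification
#'
#' Each trait gets a transform tag (`identity`, `log`, `sqrt`, `logit`) and an
#' offset used to move the column strictly inside the transform's domain
#' (e.g. `log(x + offset)` for zero-containing counts). For `logit` the
#' offset shifts the column, which must then lie strictly inside (0, 1).
#'
#' @param tags named character vector: trait -> tag.
#' @param offsets named numeric vector of per-trait offsets; traits absent
#'   from `offsets` get 0.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(tags, offsets = NULL) {
  tags <- vapply(tags, as.character, character(1L))
  ok <- c("identity", "log", "sqrt", "logit")
  if (!all(tags %in% ok)) stop("tags must be one of: ", paste(ok, collapse = ", "))
  if (is.null(names(tags)) || any(names(tags) == "")) stop("tags must be named by trait")
  off <- structure(rep(0, length(tags)), names = names(tags))
  if (!is.null(offsets)) off[names(offsets)] <- as.numeric(offsets)
  structure(list(tags = tags, offsets = off), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("transform_spec:\n")
  for (nm in names(x$tags)) {
    cat("  ", nm, ": ", x$tags[[nm]],
        if (x$offsets[[nm]] != 0) paste0(" (offset ", format(x$offsets[[nm]]), ")") else "",
        "\n", sep = "")
  }
  invisible(x)
}

transform_forward <- function(x, tag, offset, trait) {
  y <- x + offset
  switch(tag,
    identity = x,
    log = {
      if (any(y <= 0, na.rm = TRUE))
        stop("trait '", trait, "': log transform domain violation (non-positive after offset)")
      log(y)
    },
    sqrt = {
      if (any(y < 0, na.rm = TRUE))
        stop("trait '", trait, "': sqrt transform domain violation (negative after offset)")
      sqrt(y)
    },
    logit = {
      if (any(y <= 0 | y >= 1, na.rm = TRUE))
        stop("trait '", trait, "': logit transform domain violation (outside (0, 1) after offset)")
      log(y / (1 - y))
    })
}

transform_backward <- function(z, tag, offset) {
  switch(tag,
    identity = z,
    log = exp(z) - offset,
    sqrt = z^2 - offset,
    logit = stats::plogis(z) - offset)
}

#' Apply (or invert) normalising transforms on a trait table
#'
#' Transforms are applied element-wise; missing cells stay missing; traits
#' absent from the spec are left untouched. `invert_transform()` recovers the
#' original table to within 1e-10.
#'
#' @param table a [trait_table()].
#' @param spec a [transform_spec()].
#' @return A transformed [trait_table()].
#' @export
apply_transform <- function(table, spec) {
  stopifnot(inherits(table, "trait_table"), inherits(spec, "transform_spec"))
  vals <- table$values
  for (nm in intersect(names(spec$tags), names(vals))) {
    vals[[nm]] <- transform_forward(vals[[nm]], spec$tags[[nm]], spec$offsets[[nm]], nm)
  }
  trait_table_replace(table, vals)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(table, spec) {
  stopifnot(inherits(table, "trait_table"), inherits(spec, "transform_spec"))
  vals <- table$values
  for (nm in intersect(names(spec$tags), names(vals))) {
    vals[[nm]] <- transform_backward(vals[[nm]], spec$tags[[nm]], spec$offsets[[nm]])
  }
  trait_table_replace(table, vals)
}

# sample skewness; 0 for (near-)constant columns
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 < .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Choose normalising transforms by skewness minimisation
#'
#' For each trait the candidate transforms (`identity`, `log`, `sqrt`,
#' `logit`) applicable on the observed range (after an automatic offset for
#' `log`/`sqrt` on zero-containing columns) are compared by absolute sample
#' skewness of the transformed values; the minimiser wins, with ties broken
#' in the order identity, log, sqrt, logit. Constant columns get `identity`.
#' A user-supplied [transform_spec()] always overrides this automation.
#'
#' @param table a [trait_table()].
#' @return A [transform_spec()] covering every trait.
#' @export
select_transforms <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  tags <- character(0); offs <- numeric(0)
  for (nm in table$trait_names) {
    x <- table$values[[nm]]
    xo <- x[!is.na(x)]
    if (length(xo) == 0L) stop("trait '", nm, "' has no observed values")
    if (length(xo) < 10L) stop("trait '", nm, "' has fewer than 10 observed values")
    cand_tags <- "identity"; cand_offs <- 0
    rng <- range(xo)
    span <- max(diff(rng), 1e-8)
    log_off <- if (rng[1L] > 0) 0 else -rng[1L] + 0.01 * span
    cand_tags <- c(cand_tags, "log"); cand_offs <- c(cand_offs, log_off)
    sqrt_off <- if (rng[1L] >= 0) 0 else -rng[1L]
    cand_tags <- c(cand_tags, "sqrt"); cand_offs <- c(cand_offs, sqrt_off)
    if (rng[1L] > 0 && rng[2L] < 1) {
      cand_tags <- c(cand_tags, "logit"); cand_offs <- c(cand_offs, 0)
    }
    skew <- mapply(function(tg, of) {
      abs(sample_skewness(transform_forward(xo, tg, of, nm)))
    }, cand_tags, cand_offs)
    best <- which.min(skew)  # which.min takes the first minimum: preference order
    tags[nm] <- cand_tags[best]
    offs[nm] <- cand_offs[best]
  }
  transform_spec(tags, offs)
}

#' Read/write a transform specification as YAML
#'
#' @param spec a [transform_spec()].
#' @param path file path.
#' @return `read_transform_spec_yaml` returns a `transform_spec`; the writer
#'   returns `path` invisibly.
#' @export
write_transform_spec_yaml <- function(spec, path) {
  obj <- lapply(names(spec$tags), function(nm) {
    list(trait = nm, tag = unname(spec$tags[[nm]]), offset = unname(spec$offsets[[nm]]))
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_transform_spec_yaml
#' @export
read_transform_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  tags <- vapply(obj, function(e) e$tag, character(1L))
  names(tags) <- vapply(obj, function(e) e$trait, character(1L))
  offs <- vapply(obj, function(e) as.numeric(e$offset), numeric(1L))
  names(offs) <- names(tags)
  transform_spec(tags, offs)
}
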