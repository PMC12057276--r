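#' Assemble the Lin-clustering matrix
#'
#' Rows are genomes, columns are protein families; cell (g, f) holds the
#' Lin-cluster label of genome g in family f, or `NA` when g has no sequence
#' in f. Genomes with no sequence in any family are dropped with a warning.
#'
#' @param clusterings list of `lin_clustering` objects, one per family.
#' @param genomes optional character vector declaring the full genome set
#'   (defaults to the union over clusterings).
#' @return an integer matrix with genome rownames and family colnames.
#' @export
build_label_matrix <- function(clusterings, genomes = NULL) {
  stopifnot(length(clusterings) >= 1L)
  fams <- vapply(clusterings, `[[`, character(1), "family_id")
  if (anyDuplicated(fams))
    stop("duplicate family_id among clusterings: ",
         paste(unique(fams[duplicated(fams)]), collapse = ", "))
  seen <- unique(unlist(lapply(clusterings,
                               function(cl) names(cl$assignment))))
  if (is.null(genomes)) genomes <- seen
  dropped <- setdiff(genomes, seen)
  if (length(dropped)) {
    warning("dropping genome(s) with no sequence in any family: ",
            paste(dropped, collapse = ", "))
    genomes <- setdiff(genomes, dropped)
  }
  if (length(genomes) == 0L) stop("empty dataset: no genomes retained")
  m <- matrix(NA_integer_, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  for (cl in clusterings) {
    g <- intersect(names(cl$assignment), genomes)
    m[g, cl$family_id] <- cl$assignment[g]
  }
  m
}

#' Canonical ordering of the Lin-clustering matrix
#'
#' Reproducibility requires a fixed order regardless of input order.
#' Columns (families) are sorted by ascending number of Lin-clusters, then
#' ascending canonical hash of the family name. Rows (genomes) are sorted by
#' the lexicographic order of their label vector in that column order, with
#' a missing label sorting after any integer, then by ascending canonical
#' hash of the genome name.
#'
#' @param m integer label matrix from [build_label_matrix()].
#' @return the same matrix with rows and columns permuted canonically.
#' @export
canonical_order <- function(m) {
  n_clusters <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) 0L else max(x)
  })
  col_ord <- order(n_clusters, canonical_hash(colnames(m)), method = "radix")
  m <- m[, col_ord, drop = FALSE]
  keys <- as.data.frame(m)
  keys[] <- lapply(keys, function(x) { x[is.na(x)] <- .Machine$integer.max; x })
  keys$..hash <- canonical_hash(rownames(m))
  row_ord <- do.call(order, c(unname(as.list(keys)), list(method = "radix")))
  m[row_ord, , drop = FALSE]
}

#' Collapse identical label vectors into EGGs
#'
#' Genomes sharing an identical Lin-combination (the full label vector,
#' missingness pattern included) are fused into one elementary group of
#' genomes (EGG). EGG ids are assigned 1..E in canonical row order.
#'
#' @param m a canonically ordered label matrix (see [canonical_order()]).
#' @return an object of class `egg_set`: `labels` (EGG x family integer
#'   matrix, rownames are egg ids), `genomes` (list of member genome
#'   vectors), `sizes` (integer), `genome2egg` (named integer vector).
#' @export
collapse_to_eggs <- function(m) {
  key <- apply(m, 1, function(r) {
    r <- as.character(r); r[is.na(r)] <- MISSING_TOKEN
    paste(r, collapse = "\r")
  })
  first <- !duplicated(key)
  egg_of_key <- stats::setNames(cumsum(first)[first], key[first])
  genome2egg <- stats::setNames(unname(egg_of_key[key]), rownames(m))
  labels <- m[first, , drop = FALSE]
  rownames(labels) <- as.character(seq_len(nrow(labels)))
  genomes <- unname(split(rownames(m), genome2egg))
  structure(list(labels = labels, genomes = genomes,
                 sizes = lengths(genomes), genome2egg = genome2egg),
            class = "egg_set")
}

#' @export
print.egg_set <- function(x, ...) {
  cat("<egg_set>", nrow(x$labels), "EGGs over", length(x$genome2egg),
      "genomes,", ncol(x$labels), "families\n")
  invisible(x)
}

# (family, label) token set of one EGG row; NA positions are omitted.
egg_label_tokens <- function(labels_row) {
  keep <- !is.na(labels_row)
  paste(names(labels_row)[keep], labels_row[keep], sep = ":")
}
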