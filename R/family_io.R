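#' Read one protein family from a FASTA file
#'
#' A protein family is a set of unaligned homologous amino-acid sequences,
#' each owned by exactly one genome (single-copy assumption). The genome
#' identifier is extracted from the FASTA header: by default the token before
#' the first whitespace; if `genome_delim` is given, the part of that token
#' before the first occurrence of the delimiter (for `genome|protein` style
#' headers).
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param family_id identifier of the family (defaults to the file name
#'   without extension).
#' @param genome_delim optional single character splitting genome from
#'   protein id within the header token, e.g. `"|"`. `NULL` keeps the whole
#'   token.
#' @return an object of class `protein_family`: a list with `family_id` and
#'   `records`, a data.frame with columns `seq_id`, `genome_id`, `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">gA", "MKVLAW", ">gB", "MKVLAT"), fa)
#' fam <- read_family_fasta(fa, "uL1")
#' nrow(fam$records)
#' @export
read_family_fasta <- function(path, family_id = NULL,
                              genome_delim = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(family_id))
    family_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("no sequences in FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA at line ", nonblank[1], " of ", path,
         ": expected '>' header")
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  seq_id <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1L)
  genome_id <- seq_id
  if (!is.null(genome_delim))
    genome_id <- vapply(strsplit(genome_id, genome_delim, fixed = TRUE),
                        `[`, character(1), 1L)
  residues <- as.character(seqs)
  if (any(!nzchar(residues)))
    stop("empty sequence for ", seq_id[!nzchar(residues)][1],
         " in family ", family_id)
  protein_family(family_id, seq_id, genome_id, residues)
}

#' Construct a protein family from parsed components
#'
#' @param family_id family identifier.
#' @param seq_id,genome_id,residues parallel character vectors.
#' @return a `protein_family` object.
#' @export
protein_family <- function(family_id, seq_id, genome_id, residues) {
  stopifnot(length(seq_id) == length(genome_id),
            length(seq_id) == length(residues))
  if (length(seq_id) == 0L) stop("no sequences in family ", family_id)
  dup <- unique(genome_id[duplicated(genome_id)])
  if (length(dup))
    stop("single-copy violation in family ", family_id,
         ": genome(s) with multiple sequences: ", paste(dup, collapse = ", "))
  structure(
    list(family_id = family_id,
         records = data.frame(seq_id = seq_id, genome_id = genome_id,
                              residues = residues,
                              stringsAsFactors = FALSE)),
    class = "protein_family")
}

#' @export
print.protein_family <- function(x, ...) {
  cat("<protein_family>", x$family_id, ":", nrow(x$records),
      "sequences /", length(unique(x$records$genome_id)), "genomes\n")
  invisible(x)
}

#' Read a genome priority-score table
#'
#' Two-column TSV `genome_id<TAB>score` (header optional, detected when the
#' second field of the first row is non-numeric and equals "score"). Scores
#' are real numbers; higher is preferred at the first tier of representative
#' selection. Genomes absent from the table have score 0.
#'
#' @param path path to the TSV file.
#' @return a named numeric vector of class `priority_table`.
#' @seealso [priority_score()]
#' @export
read_priority_table <- function(path) {
  if (!file.exists(path)) stop("priority table not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(priority_table(character(0), numeric(0)))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(priority_table(character(0), numeric(0)))
  if (ncol(raw) < 2L) stop("priority table must have 2 tab-separated columns")
  if (identical(tolower(raw[1, 2]), "score")) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) return(priority_table(character(0), numeric(0)))
  score <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad))
    stop("non-numeric or non-finite priority score at row ", bad[1],
         ": '", raw[bad[1], 2], "'")
  priority_table(raw[[1]], score)
}

#' @rdname read_priority_table
#' @param genome_id,score parallel vectors defining the table directly.
#' @export
priority_table <- function(genome_id, score) {
  stopifnot(length(genome_id) == length(score), all(is.finite(score)))
  structure(stats::setNames(as.numeric(score), genome_id),
            class = "priority_table")
}

#' Look up priority scores
#'
#' @param table a `priority_table` (or `NULL`, meaning all zero).
#' @param genome_id character vector of genomes to look up.
#' @return numeric vector of scores; genomes absent from the table score 0.
#' @export
priority_score <- function(table, genome_id) {
  if (is.null(table)) return(rep(0, length(genome_id)))
  out <- unclass(table)[genome_id]
  out[is.na(out)] <- 0
  unname(out)
}

## ---- TSV writers/readers for intermediate artifacts -----------------------

format_labels <- function(m) {
  out <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  out[is.na(out)] <- MISSING_TOKEN
  out
}

#' Write / read a label matrix TSV
#'
#' First column `genome_id` (or `egg_id`), then one column per protein
#' family. Missing labels are written as `-`.
#'
#' @param m integer label matrix (rows genomes or EGGs, columns families,
#'   `NA` = missing).
#' @param path output path.
#' @param id_col name of the identifier column.
#' @return `write_label_matrix` returns `path` invisibly;
#'   `read_label_matrix` returns the integer matrix.
#' @export
write_label_matrix <- function(m, path, id_col = "genome_id") {
  df <- data.frame(rownames(m), format_labels(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == MISSING_TOKEN] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a similarity matrix as sparse triplets
#'
#' One row per unordered EGG pair with `egg_i < egg_j`; the unit diagonal is
#' implicit. Values below `floor` are omitted.
#'
#' @param sim symmetric Dice matrix with EGG ids as dimnames.
#' @param path output path.
#' @param floor smallest value stored (default 0 keeps explicit zeros out).
#' @return `write_similarity_triplets` returns `path` invisibly;
#'   `read_similarity_triplets` returns a data.frame
#'   `egg_i`, `egg_j`, `dice`.
#' @export
write_similarity_triplets <- function(sim, path, floor = 0) {
  ids <- rownames(sim)
  idx <- which(upper.tri(sim) & sim > floor, arr.ind = TRUE)
  df <- data.frame(egg_i = ids[idx[, 1]], egg_j = ids[idx[, 2]],
                   dice = sim[idx], stringsAsFactors = FALSE)
  df <- df[order(as.integer(df$egg_i), as.integer(df$egg_j)), , drop = FALSE]
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_similarity_triplets
#' @export
read_similarity_triplets <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  df
}

#' Write all pipeline outputs for a completed run
#'
#' Mirrors the tool contract of returning the representative list, the
#' genome-to-representative correspondence, and all intermediate results:
#' the Lin-clustering matrix, the Lin-combination matrix, the component
#' assignment, per-component similarity triplets, and per-threshold
#' representative and mapping tables. All tables follow the canonical
#' ordering, so reruns are byte-identical.
#'
#' @param run an `mps_run` object from [mps_run()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the character vector of files written.
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "mps_run"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  w <- function(name) file.path(out_dir, name)

  files <- c(files, write_label_matrix(run$label_matrix,
                                       w("lin_clustering_matrix.tsv")))
  egg_m <- run$eggs$labels
  files <- c(files, write_label_matrix(egg_m, w("lin_combination_matrix.tsv"),
                                       id_col = "egg_id"))
  comp_df <- data.frame(egg_id = seq_along(run$components$egg2component),
                        component_id = run$components$egg2component)
  f <- w("components.tsv")
  utils::write.table(comp_df, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  files <- c(files, f)
  for (ci in seq_along(run$similarities)) {
    f <- w(sprintf("similarity_component_%d.tsv", ci))
    files <- c(files, write_similarity_triplets(run$similarities[[ci]], f))
  }
  for (res in run$results) {
    tag <- formatC(res$delta, format = "g")
    f <- w(sprintf("representatives_delta_%s.tsv", tag))
    utils::write.table(res$representatives, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    files <- c(files, f)
    f <- w(sprintf("mapping_delta_%s.tsv", tag))
    utils::write.table(res$mapping, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    files <- c(files, f)
  }
  invisible(files)
}
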