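# Readers and writers for the standard formats the pipeline consumes.

#' Read a FASTA file
#'
#' @param path FASTA file (protein or nucleotide; LF or CRLF line endings).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return data.frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) {
      if (length(p)) as.character(p)[1] else NA_character_
    }, character(1))
  } else rep(NA_character_, nrow(df))
  data.frame(seqid = as.character(df$seqnames), type = as.character(df$type),
             start = df$start, end = df$end,
             strand = as.character(df$strand),
             ID = if ("ID" %in% names(df)) as.character(df$ID)
                  else NA_character_,
             Parent = parent, stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' @param gff data.frame as returned by [read_gff3()] or
#'   [simulate_gene_models()].
#' @param path Output path.
#' @export
write_gff3 <- function(gff, path) {
  attr_col <- ifelse(is.na(gff$Parent),
                     sprintf("ID=%s", gff$ID),
                     sprintf("ID=%s;Parent=%s", gff$ID, gff$Parent))
  lines <- sprintf("%s\tmybscope\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   gff$seqid, gff$type, gff$start, gff$end, gff$strand,
                   attr_col)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file or string.
#' @return An `ape::phylo` tree (branch lengths and internal labels
#'   preserved).
#' @export
read_newick <- function(path) {
  as_phylo(path)
}

#' Read a numeric TSV matrix (rows = genes, columns = samples)
#'
#' @param path TSV with row names in the first column.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a numeric matrix as TSV
#'
#' @param matrix Matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results data.frame as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read motif matrices from TSV
#'
#' Expects rows = positions and the 20 residue columns (any order).
#'
#' @param path TSV path.
#' @param motif_id Motif identifier (default: file base name).
#' @return A `motif_matrix`.
#' @export
read_motif_tsv <- function(path, motif_id = NULL) {
  if (is.null(motif_id)) {
    motif_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, check.names = FALSE)
  motif_matrix(as.matrix(df[, AA_STANDARD]), motif_id)
}

#' Write a motif matrix to TSV
#'
#' @param motif A `motif_matrix`.
#' @param path Output path.
#' @export
write_motif_tsv <- function(motif, path) {
  utils::write.table(as.data.frame(motif$mat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' Parses the `MOTIF` / `letter-probability matrix` blocks of the MEME
#' minimal format for protein alphabets.
#'
#' @param path MEME minimal text file.
#' @return Named list of `motif_matrix` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  alphabet <- if (length(alpha_line)) {
    str_chars(trimws(sub("^ALPHABET\\s*=?\\s*", "", alpha_line[1])))
  } else AA_STANDARD
  motif_starts <- grep("^MOTIF\\s", lines)
  if (!length(motif_starts)) {
    stop("no MOTIF blocks in ", path, call. = FALSE)
  }
  out <- list()
  for (s in motif_starts) {
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1]][1]
    hdr <- grep("letter-probability matrix", lines[seq(s, length(lines))])[1]
    hdr <- s + hdr - 1L
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    colnames(mat) <- alphabet
    # renormalize printed-precision rows
    mat <- mat / rowSums(mat)
    out[[id]] <- motif_matrix(mat, id)
  }
  out
}
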