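#' Read a FASTQ file into a table of sequence records
#'
#' Reads plain (uncompressed or gzipped) Sanger/Phred+33 FASTQ. Records are
#' returned in file order as a data frame, one row per read. Malformed
#' records -- a quality string whose length differs from the sequence, a
#' header not starting with `@`, or a truncated trailing record -- raise an
#' error naming the 1-based record index.
#'
#' @param path path to a FASTQ file (4 lines per record).
#' @param sample_id sample label attached to every record (the caller's
#'   context; FASTQ itself carries none).
#' @return data.frame with columns `read_id`, `sequence`, `quality`,
#'   `sample_id`.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), sample_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop(sprintf("truncated FASTQ record %d in %s",
                 length(lines) %/% 4 + 1, path))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in %s (bad header or '+' line)",
                 bad[1], path))
  }
  bad <- which(nchar(seqs) != nchar(qual) | nchar(seqs) == 0)
  if (length(bad)) {
    stop(sprintf(
      "malformed FASTQ record %d in %s (sequence/quality length mismatch)",
      bad[1], path))
  }
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
             sequence = toupper(seqs), quality = qual,
             sample_id = rep(sample_id, n), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTQ
#'
#' @param records data.frame as returned by [read_fastq()]; if the `quality`
#'   column is absent, a constant `"I"` (Phred 40) is written.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  qual <- records$quality
  if (is.null(qual)) {
    qual <- vapply(nchar(records$sequence),
                   function(n) strrep("I", n), character(1))
  }
  out <- as.vector(rbind(paste0("@", records$read_id), records$sequence,
                         "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a TSV count table
#'
#' Canonical table dialect: tab-separated, no quoting, UTF-8; first column
#' holds feature ids, the header row sample ids. Cells must be non-negative
#' integers; violations are reported with their row and column.
#'
#' @param path path to the TSV file.
#' @param feature_kind passed to [count_matrix()].
#' @param normalized set `TRUE` to accept fractional values.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, feature_kind = "ASV", normalized = FALSE) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 1) stop("count table has no columns: ", path)
  fid <- df[[1]]
  dup <- fid[duplicated(fid)]
  if (length(dup)) {
    stop("duplicated feature id in ", path, ": ", dup[1])
  }
  m <- matrix(0, nrow(df), ncol(df) - 1L,
              dimnames = list(fid, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("invalid count at row '%s', column '%s' in %s",
                   fid[bad[1]], colnames(df)[j + 1L], path))
    }
    m[, j] <- v
  }
  count_matrix(m, feature_kind = feature_kind, normalized = normalized)
}

#' Write a count matrix as TSV
#'
#' Lossless round-trip partner of [read_count_table()]; an empty matrix
#' yields a header-only file.
#'
#' @param matrix a [count_matrix()].
#' @param path output path.
#' @param id_column name for the first (feature id) column.
#' @export
write_count_table <- function(matrix, path, id_column = "feature_id") {
  stopifnot(is_count_matrix(matrix))
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(ids, as.data.frame(unclass(matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(matrix))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector (names become headers), or a list
#'   of OBU clusters as produced by [run_obu_pipeline()] (centroids are
#'   written, named by cluster id).
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.list(sequences) && !is.null(sequences[[1]]$centroid)) {
    ids <- vapply(sequences, function(cl) cl$obu_id, character(1))
    sequences <- setNames(
      vapply(sequences, function(cl) cl$centroid, character(1)), ids)
  }
  if (length(sequences) &&
      (is.null(names(sequences)) || any(names(sequences) == ""))) {
    stop("every FASTA sequence needs a name")
  }
  if (any(nchar(sequences) == 0)) {
    stop("empty sequence for: ",
         names(sequences)[which(nchar(sequences) == 0)[1]])
  }
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             as.character(sequences))), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0) {
    if (length(lines) == 0) return(setNames(character(), character()))
    stop("not a FASTA file: ", path)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1L, ends[i])][hdr[i] + 1L <= ends[i]],
          collapse = "")
  }, character(1))
  setNames(toupper(seqs), sub("\\s.*$", "", sub("^>", "", lines[hdr])))
}

#' Read a 7-rank taxonomy table
#'
#' TSV with a `feature_id` column and the seven ranks domain..species.
#' Missing ranks must already use (or are rewritten to) the token
#' `unclassified_<parent>`, so genus-level aggregation is total.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `feature_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("feature_id", tax_ranks())
  miss <- setdiff(need, colnames(tax))
  if (length(miss)) stop("taxonomy file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tax$feature_id)) {
    stop("duplicated feature_id in taxonomy: ",
         tax$feature_id[duplicated(tax$feature_id)][1])
  }
  fill_unclassified(tax[need])
}

#' @export
#' @rdname read_taxonomy
#' @param taxonomy a taxonomy data.frame.
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Fill missing taxonomy ranks with unclassified tokens
#'
#' Replaces empty/NA ranks with `unclassified_<nearest classified parent>`,
#' enforcing that no rank is assigned below an unassigned one.
#'
#' @param taxonomy data.frame with `feature_id` plus the 7 rank columns.
#' @return the completed data.frame.
#' @export
fill_unclassified <- function(taxonomy) {
  ranks <- tax_ranks()
  for (i in seq_len(nrow(taxonomy))) {
    parent <- "root"
    seen_gap <- FALSE
    for (r in ranks) {
      v <- taxonomy[i, r]
      assigned <- !is.na(v) && nzchar(v) && !startsWith(v, "unclassified")
      if (assigned && seen_gap) {
        stop(sprintf("feature '%s': rank '%s' assigned below an unassigned rank",
                     taxonomy$feature_id[i], r))
      }
      if (!assigned) {
        taxonomy[i, r] <- paste0("unclassified_", parent)
        seen_gap <- TRUE
      } else {
        parent <- v
      }
    }
  }
  taxonomy
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `source` (seawater/sediment/soil),
#' `medium` (none/MBA/MBG/SWA/SWG) and `replicate`.
#'
#' @param path path to the TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "source", "medium", "replicate")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicated sample_id in metadata")
  md
}

#' @export
#' @rdname read_sample_metadata
#' @param metadata data.frame of sample metadata.
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# every sample in the matrix must have metadata
check_metadata_cover <- function(matrix, metadata) {
  miss <- setdiff(colnames(matrix), metadata$sample_id)
  if (length(miss)) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
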