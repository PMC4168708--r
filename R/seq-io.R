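#' @useDynLib xmb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom runif setNames quantile rpois ks.test uniroot ppois
#' @importFrom utils head tail write.table read.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Normalize a DNA string to the ACGT alphabet
#'
#' Uppercases the input and replaces every non-ACGT character by a
#' deterministic pseudo-random base keyed on its position, so that repeated
#' reads of the same file give the same sequence without touching the global
#' RNG. The model underlying this package has no ambiguity codes, so N and
#' friends must be resolved to concrete bases.
#'
#' @param x character vector of sequences.
#' @param quiet suppress the replacement-count message.
#' @return character vector over \{A,C,G,T\}.
#' @export
normalize_bases <- function(x, quiet = FALSE) {
  x <- toupper(x)
  n_replaced <- 0L
  out <- vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% DNA_ALPHABET)
    if (length(bad)) {
      # multiplicative hash of the 1-based position, mapped to a base
      h <- (bad * 2654435761) %% 2^31
      ch[bad] <- DNA_ALPHABET[(h %% 4) + 1]
      n_replaced <<- n_replaced + length(bad)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (n_replaced > 0 && !quiet) {
    message("normalize_bases: replaced ", n_replaced, " non-ACGT characters")
  }
  out
}

#' Read a FASTA file
#'
#' @param path file path.
#' @param normalize normalize to uppercase ACGT (default TRUE).
#' @return data.frame with columns `id`, `bases`, `qualities` (NA for FASTA).
#' @export
read_fasta <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty)) {
    first <- nonempty[1]
    if (!startsWith(lines[first], ">")) {
      stop("read_fasta: line ", first, ": expected FASTA header '>'")
    }
    hdr <- which(startsWith(lines, ">"))
    ends <- c(hdr[-1] - 1L, length(lines))
    for (k in seq_along(hdr)) {
      body <- lines[seq2(hdr[k] + 1L, ends[k])]
      if (!any(nzchar(trimws(body)))) {
        stop("read_fasta: line ", hdr[k], ": record has empty sequence")
      }
    }
  }
  set <- Biostrings::readBStringSet(path)
  bases <- as.character(set)
  if (normalize) bases <- normalize_bases(bases)
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    bases = unname(bases),
    qualities = NA_character_,
    stringsAsFactors = FALSE
  )
}

# seq() that returns integer(0) for from > to
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Write records to FASTA
#'
#' @param records data.frame with `id` and `bases` columns.
#' @param path output path.
#' @param line_width wrap width (>= 1).
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  stopifnot(line_width >= 1)
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(setNames(records$bases, records$id))
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Read a 4-line-per-record FASTQ file
#'
#' @param path file path.
#' @param normalize normalize bases (default TRUE).
#' @return data.frame with `id`, `bases`, `qualities`.
#' @export
read_fastq <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("read_fastq: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    stop("read_fastq: line count ", length(lines), " is not a multiple of 4")
  }
  n <- length(lines) %/% 4
  idx <- seq_len(n)
  ids <- lines[4 * idx - 3]
  if (n > 0 && !all(startsWith(ids, "@"))) {
    bad <- which(!startsWith(ids, "@"))[1]
    stop("read_fastq: line ", 4 * bad - 3, ": expected '@' header")
  }
  bases <- lines[4 * idx - 2]
  quals <- lines[4 * idx]
  mism <- which(nchar(bases) != nchar(quals))
  if (length(mism)) {
    stop("read_fastq: line ", 4 * mism[1], ": quality length does not match sequence length")
  }
  if (normalize) bases <- normalize_bases(bases)
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", ids)),
    bases = bases, qualities = quals, stringsAsFactors = FALSE
  )
}

#' Write records to FASTQ
#'
#' Records without qualities get the constant placeholder "I" (the simulators
#' in this package are parametric, not quality-driven).
#'
#' @param records data.frame with `id`, `bases` and optional `qualities`.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  quals <- records$qualities
  if (is.null(quals)) quals <- rep(NA_character_, nrow(records))
  missing_q <- is.na(quals)
  quals[missing_q] <- strrep("I", nchar(records$bases[missing_q]))
  out <- character(4 * nrow(records))
  idx <- seq_len(nrow(records))
  out[4 * idx - 3] <- paste0("@", records$id)
  out[4 * idx - 2] <- records$bases
  out[4 * idx - 1] <- "+"
  out[4 * idx] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Write the ground-truth sidecar for a simulated genome or read set
#'
#' Planted-repeat coordinates and read origins are serialized as a structured
#' text file so that oracle tests never have to re-infer the truth.
#'
#' @param obj an `xmb_genome` or `xmb_reads` object.
#' @param path output path.
#' @export
write_truth <- function(obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(obj, "xmb_genome")) {
    writeLines(c("# xmb genome truth", paste0("G\t", nchar(obj$bases)),
                 paste0("circular\t", as.integer(obj$circular))), con)
    for (occ in obj$truth) {
      writeLines(paste0(
        "repeat\t", occ$kind, "\t",
        paste(occ$copy_starts, collapse = ","), "\t",
        occ$flanked_length, "\t",
        paste(occ$polymorphism_sites, collapse = ","), "\t",
        paste(apply(occ$site_bases, 1, paste, collapse = ""), collapse = ",")
      ), con)
    }
  } else if (inherits(obj, "xmb_reads")) {
    writeLines(c("# xmb read truth", "id\ttruth_start"), con)
    writeLines(paste0(seq_along(obj$truth_start), "\t", obj$truth_start), con)
  } else {
    stop("write_truth: unsupported object")
  }
  invisible(path)
}
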