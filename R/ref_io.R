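## Reference FASTA input/output and synthetic reference fixtures.
##
## A ReferenceSet is the per-organism container: an organism label plus an
## ordered, named character vector of contig sequences (uppercase ACGTN).
## Parsing is delegated to Biostrings; normalisation (uppercasing, IUPAC
## ambiguity -> N) and the validation contract live here.

#' Construct a reference set
#'
#' @param organism organism label (from the sample design, never from
#'   FASTA headers).
#' @param contigs named character vector of nucleotide sequences; names
#'   are contig ids and must be unique.
#' @return an object of class `reference_set` with elements `organism`,
#'   `contigs`, `lengths` and `total_length`.
#' @export
reference_set <- function(organism, contigs) {
  stopifnot(is_string(organism), is.character(contigs), length(contigs) >= 1)
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop("all contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop("duplicate contig id in reference for '", organism, "': ",
         names(contigs)[duplicated(names(contigs))][1])
  }
  if (any(nchar(contigs) == 0)) {
    stop("empty sequence for contig '",
         names(contigs)[nchar(contigs) == 0][1], "' (", organism, ")")
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("non-normalised characters in contig '", names(contigs)[bad][1],
         "'; use read_fasta() or normalize_sequence()")
  }
  structure(
    list(organism = organism,
         contigs = contigs,
         lengths = stats::setNames(nchar(contigs), names(contigs)),
         total_length = sum(nchar(contigs))),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> organism:", x$organism, "-", length(x$contigs),
      "contig(s),", x$total_length, "bp\n")
  invisible(x)
}

#' Normalize a nucleotide sequence
#'
#' Uppercases and replaces IUPAC ambiguity codes other than N (and any
#' other non-ACGTN letter) with N. Idempotent.
#'
#' @param x character vector of sequences.
#' @return list with `sequence` (normalized vector) and `n_replaced`
#'   (total count of characters converted to N).
#' @export
normalize_sequence <- function(x) {
  up <- toupper(x)
  n_before <- sum(nchar(gsub("[ACGTN]", "", up)))
  list(sequence = gsub("[^ACGTN]", "N", up), n_replaced = n_before)
}

#' Read a reference FASTA file into a reference set
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than N are
#' replaced by N (a warning reports how many characters were converted).
#' Multi-line records are concatenated. Gzip-compressed input is
#' accepted (detected by the `.gz` extension).
#'
#' @param path path to a FASTA (optionally gzipped) file.
#' @param organism organism label to attach; defaults to the file name
#'   without extension. Labels always come from the sample design --
#'   FASTA headers only identify contigs.
#' @return a [reference_set()].
#' @export
read_fasta <- function(path, organism = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(organism)) {
    organism <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                    basename(path), ignore.case = TRUE)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header token '", ids[duplicated(ids)][1],
         "' in ", path)
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0)) {
    stop("record '", ids[nchar(seqs) == 0][1], "' in ", path,
         " has an empty sequence")
  }
  norm <- normalize_sequence(seqs)
  if (norm$n_replaced > 0) {
    warning(norm$n_replaced, " ambiguity/non-ACGTN character(s) replaced ",
            "by N while reading ", path, call. = FALSE)
  }
  reference_set(organism, stats::setNames(norm$sequence, ids))
}

#' Write sequences to a FASTA file
#'
#' @param reads a named character vector of sequences (names become
#'   headers), a list of `simulated_read` objects, or a `reference_set`.
#' @param path output path.
#' @param line_width bases per sequence line (default 80).
#' @param append append to an existing file instead of truncating.
#' @return number of records written, invisibly.
#' @export
write_fasta <- function(reads, path, line_width = 80L, append = FALSE) {
  stopifnot(is_count(line_width, min = 1L))
  if (inherits(reads, "reference_set")) reads <- reads$contigs
  if (is.list(reads)) {
    reads <- stats::setNames(
      vapply(reads, function(r) r$sequence, character(1)),
      vapply(reads, function(r) r$id, character(1)))
  }
  if (length(reads) == 0) {
    if (!append) {
      ok <- file.create(path)
      if (!ok) stop("cannot write to ", path)
    }
    return(invisible(0L))
  }
  con <- tryCatch(file(path, if (append) "ab" else "wb"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  for (i in seq_along(reads)) {
    s <- reads[[i]]
    starts <- seq.int(1L, nchar(s), by = line_width)
    writeLines(c(paste0(">", names(reads)[i]),
                 substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))),
               con)
  }
  invisible(length(reads))
}

#' Generate a random synthetic reference
#'
#' Draws i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2. A pure function of its arguments: the same seed always
#' yields byte-identical sequences. Intended as the test and
#' demonstration fixture generator (stands in for real assemblies).
#'
#' @param organism organism label.
#' @param n_contigs number of contigs (>= 1).
#' @param contig_length length of each contig in bases (scalar or one
#'   value per contig).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer random seed.
#' @return a [reference_set()] with contigs named `"<organism>_c<i>"`.
#' @export
generate_random_reference <- function(organism, n_contigs = 1L,
                                      contig_length = 10000L, gc = 0.5,
                                      seed = 1L) {
  stopifnot(is_count(n_contigs, 1L), all(contig_length >= 1))
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("gc must be a fraction in [0, 1], got ", gc)
  }
  lens <- rep_len(as.integer(contig_length), n_contigs)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(contigs) <- sprintf("%s_c%d", organism, seq_len(n_contigs))
  reference_set(organism, contigs)
}
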