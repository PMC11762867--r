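## Read-length drawing, locus/strand selection, fragment extraction and
## whole-sample orchestration.
##
## The length model governs the pre-error template fragment; balanced
## insertion/deletion rates keep the expected final read length equal to
## the fragment length while locus arithmetic stays exact. Reads are
## generated organism by organism, each under its own derived RNG
## substream, and streamed to FASTA in bounded-memory chunks.

#' Construct a read-length model
#'
#' Lengths are drawn from a Gaussian with the given mean and standard
#' deviation, rounded to integers, and rejected/redrawn while outside
#' `[min_len, min(max_len, contig_cap)]` (up to 1000 rounds, then
#' clamped to the nearest bound).
#'
#' @param mean mean read length in bases (> 0).
#' @param sd standard deviation in bases (>= 0; 0 gives fixed-length
#'   reads).
#' @param min_len minimum read length (default 50).
#' @param max_len optional hard maximum.
#' @return an object of class `length_model`.
#' @export
length_model <- function(mean = 2000, sd = 200, min_len = 50L,
                         max_len = NULL) {
  stopifnot(mean > 0, sd >= 0, min_len >= 1)
  if (!is.null(max_len) && max_len < min_len) {
    stop("max_len must be >= min_len")
  }
  structure(list(mean = mean, sd = sd, min_len = as.integer(min_len),
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len)),
            class = "length_model")
}

#' Draw read lengths from a length model
#'
#' @param n number of lengths to draw.
#' @param model a [length_model()].
#' @param contig_cap upper cap in bases, normally the longest contig of
#'   the organism's reference (must be >= `model$min_len`).
#' @return integer vector of `n` lengths in
#'   `[min_len, min(max_len, contig_cap)]`. Uses the current RNG state.
#' @export
draw_length <- function(n, model, contig_cap) {
  stopifnot(contig_cap >= model$min_len)
  hi <- if (is.null(model$max_len)) contig_cap else min(model$max_len, contig_cap)
  lo <- model$min_len
  lens <- as.integer(round(stats::rnorm(n, model$mean, model$sd)))
  bad <- which(lens < lo | lens > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    lens[bad] <- as.integer(round(stats::rnorm(length(bad), model$mean,
                                               model$sd)))
    bad <- which(lens < lo | lens > hi)
    tries <- tries + 1L
  }
  if (length(bad)) lens[bad] <- pmin(pmax(lens[bad], lo), hi)
  lens
}

#' Pick a genomic locus for a fragment
#'
#' The contig is chosen with probability proportional to its number of
#' valid placements (`length - frag_len + 1`) among contigs long enough
#' to hold the fragment; the start is uniform over valid placements.
#'
#' @param refset a [reference_set()].
#' @param frag_len fragment length in bases.
#' @return list with `contig` (id) and `start` (0-based inclusive);
#'   `NULL` when no contig can hold the fragment (caller should redraw
#'   a shorter length).
#' @export
pick_locus <- function(refset, frag_len) {
  w <- refset$lengths - frag_len + 1
  w[w < 0] <- 0
  if (all(w == 0)) return(NULL)
  ci <- if (length(w) == 1L) 1L else sample.int(length(w), 1L, prob = w)
  start <- sample.int(w[ci], 1L) - 1L
  list(contig = names(refset$contigs)[ci], start = as.integer(start))
}

#' Extract a fragment from a contig
#'
#' Returns the substring `[start, end)` (0-based half-open),
#' reverse-complemented when `strand` is `"-"`. N complements to N.
#'
#' @param sequence contig sequence string.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return the fragment string.
#' @export
extract_fragment <- function(sequence, start, end, strand = "+") {
  if (start < 0 || end > nchar(sequence) || start >= end) {
    stop("internal error: fragment [", start, ",", end,
         ") out of contig bounds (length ", nchar(sequence), ")")
  }
  frag <- substr(sequence, start + 1L, end)
  if (strand == "-") frag <- revcomp(frag)
  frag
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector over `{A, C, G, T, N}`.
#' @return reverse complements (N maps to N).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Generate all reads for one organism under its own RNG substream.
## Returns list(sequences = named character, truth = data.frame).
## forward_only disables the Bernoulli(0.5) strand draw.
simulate_organism <- function(refset, n_reads, model, profile, seed,
                              forward_only = FALSE, chunk_size = 20000L,
                              sink = NULL) {
  cap <- max(refset$lengths)
  if (cap < model$min_len) {
    stop("every contig of organism '", refset$organism,
         "' is shorter than min_len (", model$min_len, ")")
  }
  org <- refset$organism
  all_seqs <- character(0)
  all_truth <- vector("list", 0)
  serial <- 0L
  with_seed(seed, {
    remaining <- n_reads
    while (remaining > 0L) {
      m <- min(chunk_size, remaining)
      lens <- draw_length(m, model, cap)
      contig <- character(m); start <- integer(m)
      for (i in seq_len(m)) {
        loc <- pick_locus(refset, lens[i])
        while (is.null(loc)) { # only when some contigs < min draw; redraw
          lens[i] <- draw_length(1L, model, cap)
          loc <- pick_locus(refset, lens[i])
        }
        contig[i] <- loc$contig; start[i] <- loc$start
      }
      end <- start + lens
      strand <- if (forward_only) rep("+", m) else
        ifelse(stats::runif(m) < 0.5, "+", "-")
      frags <- substring(refset$contigs[contig], start + 1L, end)
      neg <- which(strand == "-")
      if (length(neg)) frags[neg] <- revcomp(frags[neg])
      recs <- matrix(0L, nrow = m, ncol = 3,
                     dimnames = list(NULL, c("n_sub", "n_ins", "n_del")))
      if (profile$rate_sub + profile$rate_ins + profile$rate_del > 0) {
        for (i in seq_len(m)) {
          r <- apply_errors(frags[i], profile)
          frags[i] <- r$sequence
          recs[i, ] <- r$record
        }
      }
      ids <- sprintf("%s|%s|%d|%s|%d|%d", org, contig, start, strand, lens,
                     serial + seq_len(m))
      serial <- serial + m
      truth <- data.frame(
        read_id = ids, organism = org, contig = contig, start = start,
        end = end, strand = strand, fragment_length = lens,
        n_sub = recs[, 1], n_ins = recs[, 2], n_del = recs[, 3],
        stringsAsFactors = FALSE)
      seqs <- stats::setNames(unname(frags), ids)
      if (is.null(sink)) {
        all_seqs <- c(all_seqs, seqs)
      } else {
        sink(seqs)
      }
      all_truth[[length(all_truth) + 1L]] <- truth
      remaining <- remaining - m
    }
  })
  list(sequences = if (is.null(sink)) all_seqs else NULL,
       truth = if (length(all_truth)) do.call(rbind, all_truth) else
         data.frame(read_id = character(0), organism = character(0),
                    contig = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    fragment_length = integer(0), n_sub = integer(0),
                    n_ins = integer(0), n_del = integer(0)))
}

#' Simulate a whole sample from a design
#'
#' Resolves per-organism read counts, generates each organism's reads
#' (length draw, locus, strand, fragment extraction, error injection),
#' streams them to `<name>.fasta` in the output directory and writes the
#' full report bundle (abundance, error profile, error distribution,
#' run parameters, per-read truth table). Fully deterministic given the
#' design seed: each organism draws from its own substream derived from
#' the sample seed and organism name, so config order does not change
#' another organism's reads.
#'
#' @param design a [sample_design()].
#' @param output_dir output directory (created if absent).
#' @param profile an [error_profile()] or preset name/path overriding
#'   the design's profile; `NULL` uses the design's.
#' @param seed seed overriding the design seed; `NULL` uses the
#'   design's.
#' @param name sample base name for output files; defaults to
#'   `design$name`.
#' @param line_width FASTA line width.
#' @return a `report_bundle` (see [write_report_bundle()]), invisibly
#'   containing the output file paths in `$files`.
#' @export
simulate_sample <- function(design, output_dir, profile = NULL, seed = NULL,
                            name = NULL, line_width = 80L) {
  stopifnot(inherits(design, "sample_design"))
  profile <- load_profile(if (is.null(profile)) design$profile else profile)
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  name <- if (is.null(name)) design$name else name
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  resolved <- resolve_abundances(design, seed = seed)
  refsets <- load_design_references(design)

  fasta_path <- file.path(output_dir, paste0(name, ".fasta"))
  write_fasta(character(0), fasta_path) # truncate
  truth_list <- vector("list", length(resolved$counts))
  n_written <- 0L
  for (j in seq_along(resolved$counts)) {
    org <- names(resolved$counts)[j]
    cnt <- resolved$counts[[j]]
    if (cnt == 0L) next
    sub_seed <- derive_seed(seed, "organism", org)
    res <- simulate_organism(
      refsets[[org]], cnt, design$length_model, profile, sub_seed,
      forward_only = isTRUE(design$forward_only),
      sink = function(seqs) {
        write_fasta(seqs, fasta_path, line_width = line_width, append = TRUE)
      })
    truth_list[[j]] <- res$truth
    n_written <- n_written + cnt
  }
  truth <- do.call(rbind, truth_list[!vapply(truth_list, is.null, logical(1))])
  if (is.null(truth)) {
    stop("design resolved to zero reads for every organism")
  }
  truth$template_bases <- truth$fragment_length
  dist <- summarize_errors(truth, template_bases = sum(truth$fragment_length))

  bundle <- report_bundle(
    design = design, resolved = resolved, profile = profile,
    error_distribution = dist, seed = seed, name = name)
  files <- write_report_bundle(bundle, output_dir, truth = truth)
  bundle$files <- c(fasta = fasta_path, files)
  invisible(bundle)
}
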