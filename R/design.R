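## Sample designs: the declarative description of a mock sample and its
## resolution to an exact integer read count per organism.
##
## Abundance modes: absolute (a read count), relative (a percentage of
## the sample total) or random (a share of whatever is left, drawn from
## a symmetric Dirichlet). Entries are either individual organisms or
## taxa with subtaxa (a taxon-level budget split among members). A
## host-microbiome design may flag one organism as the host absorbing
## `total - sum(everything else)` (fill_remainder), which keeps the
## total fixed across e.g. a dilution series.
##
## Resolution order: absolutes are reserved first, relatives next
## (largest-remainder rounded against their exact percentage quotas),
## random entries share the leftover, and finally the fill-remainder
## host absorbs the rest. Over-allocation is a hard error, never a
## silent rescale. The grand total is exact by construction.

#' Construct an abundance specification
#'
#' @param mode `"absolute"`, `"relative"` or `"random"`.
#' @param value read count (absolute, integer >= 0) or percentage in
#'   `[0, 100]` (relative); must be absent for random mode.
#' @return an `abundance_spec` object.
#' @export
abundance_spec <- function(mode, value = NULL) {
  mode <- match.arg(mode, c("absolute", "relative", "random"))
  if (mode == "random") {
    if (!is.null(value)) abort_design("random abundance takes no value")
  } else if (mode == "absolute") {
    if (!is_count(value)) {
      abort_design("absolute abundance must be an integer >= 0, got ",
                   deparse(value))
    }
    value <- as.integer(value)
  } else {
    if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
        value < 0 || value > 100) {
      abort_design("relative abundance must be a percentage in [0, 100], got ",
                   deparse(value))
    }
  }
  structure(list(mode = mode, value = value), class = "abundance_spec")
}

#' Construct an organism entry of a sample design
#'
#' @param name unique organism name.
#' @param reference path to the organism's FASTA reference.
#' @param abundance an [abundance_spec()]; `NULL` only for the
#'   fill-remainder host or a taxon member.
#' @param host flag the organism as the host genome.
#' @param fill_remainder host absorbs `total_reads - sum(other counts)`.
#' @return an `organism_spec` object.
#' @export
organism_spec <- function(name, reference, abundance = NULL, host = FALSE,
                          fill_remainder = FALSE) {
  stopifnot(is_string(name), is_string(reference))
  if (fill_remainder && !host) {
    abort_design("fill_remainder is only valid on the host organism ('",
                 name, "')")
  }
  if (!is.null(abundance)) stopifnot(inherits(abundance, "abundance_spec"))
  if (is.null(abundance) && !fill_remainder) {
    abort_design("organism '", name,
                 "' needs an abundance spec (or host fill_remainder)")
  }
  structure(list(name = name, reference = reference, abundance = abundance,
                 host = isTRUE(host), fill_remainder = isTRUE(fill_remainder)),
            class = "organism_spec")
}

#' Construct a taxon-with-subtaxa entry
#'
#' A read budget for a higher taxon (e.g. a species complex whose
#' members' individual abundances are unknown) distributed among member
#' organisms.
#'
#' @param label taxon label.
#' @param abundance an [abundance_spec()] for the whole taxon.
#' @param members list of [organism_spec()] WITHOUT their own abundance
#'   specs (pass `abundance = NULL` via [taxon_member()]).
#' @param split `"equal"` (floor share each, remainder to the first
#'   members in declaration order) or `"random"` (symmetric Dirichlet).
#' @return a `taxon_spec` object.
#' @export
taxon_spec <- function(label, abundance, members, split = c("equal", "random")) {
  split <- match.arg(split)
  stopifnot(is_string(label), inherits(abundance, "abundance_spec"),
            is.list(members), length(members) >= 1)
  for (m in members) {
    if (!inherits(m, "organism_spec")) {
      abort_design("taxon '", label, "' members must be organism specs")
    }
    if (!is.null(m$abundance)) {
      abort_design("taxon member '", m$name,
                   "' must not carry its own abundance (the taxon total is ",
                   "distributed)")
    }
  }
  structure(list(label = label, abundance = abundance, members = members,
                 split = split), class = "taxon_spec")
}

#' Construct a taxon member (an organism without its own abundance)
#' @param name organism name.
#' @param reference FASTA path.
#' @return an `organism_spec` with no abundance.
#' @export
taxon_member <- function(name, reference) {
  structure(list(name = name, reference = reference, abundance = NULL,
                 host = FALSE, fill_remainder = FALSE),
            class = "organism_spec")
}

#' Construct a sample design
#'
#' @param entries list of [organism_spec()] and [taxon_spec()] objects.
#' @param total_reads total reads in the sample; required whenever any
#'   entry is relative or random or a fill-remainder host is present,
#'   otherwise implied by the sum of absolute values.
#' @param scenario `"environmental"` or `"host_microbiome"`.
#' @param length_model a [length_model()].
#' @param profile error profile preset name, file path or
#'   [error_profile()].
#' @param seed integer base seed.
#' @param replicates number of replicates (used by the CLI).
#' @param name sample name used for output files.
#' @param random_alpha Dirichlet concentration for random-mode shares.
#' @param forward_only disable the per-read strand flip.
#' @return a validated `sample_design` object.
#' @export
sample_design <- function(entries, total_reads = NULL,
                          scenario = c("environmental", "host_microbiome"),
                          length_model = nanomock::length_model(),
                          profile = "perfect", seed = 1L, replicates = 1L,
                          name = "sample", random_alpha = 1,
                          forward_only = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(is.list(entries), length(entries) >= 1,
            inherits(length_model, "length_model"),
            is_count(seed, 0L), is_count(replicates, 1L), is_string(name),
            random_alpha > 0)

  org_names <- character(0)
  n_host <- 0L
  has_rel_or_rand <- FALSE
  abs_sum <- 0L
  for (e in entries) {
    if (inherits(e, "organism_spec")) {
      org_names <- c(org_names, e$name)
      if (e$fill_remainder) n_host <- n_host + 1L
      ab <- e$abundance
    } else if (inherits(e, "taxon_spec")) {
      org_names <- c(org_names, vapply(e$members, `[[`, character(1), "name"))
      ab <- e$abundance
    } else {
      abort_design("design entries must be organism or taxon specs")
    }
    if (!is.null(ab)) {
      if (ab$mode == "absolute") abs_sum <- abs_sum + ab$value
      else has_rel_or_rand <- TRUE
    }
  }
  dup <- org_names[duplicated(org_names)]
  if (length(dup)) abort_design("duplicate organism name '", dup[1], "'")
  if (n_host > 1L) abort_design("at most one fill_remainder host is allowed")
  needs_total <- has_rel_or_rand || n_host > 0L
  if (needs_total && is.null(total_reads)) {
    abort_design("total_reads is required when any entry is relative or ",
                 "random, or a fill_remainder host is present")
  }
  if (is.null(total_reads)) {
    total_reads <- abs_sum
  } else {
    if (!is_count(total_reads, 1L)) {
      abort_design("total_reads must be a positive integer")
    }
    if (!needs_total && abs_sum != total_reads) {
      abort_design("all-absolute design: sum of absolute values (", abs_sum,
                   ") must equal total_reads (", total_reads, ")")
    }
  }

  design <- structure(
    list(entries = entries, total_reads = as.integer(total_reads),
         scenario = scenario, length_model = length_model,
         profile = profile, seed = as.integer(seed),
         replicates = as.integer(replicates), name = name,
         random_alpha = random_alpha, forward_only = isTRUE(forward_only)),
    class = "sample_design")
  # fail fast on over-allocation and percentage overflow
  validate_allocation(design)
  design
}

#' @export
print.sample_design <- function(x, ...) {
  cat("<sample_design>", x$name, "-", length(x$entries), "entr(ies),",
      x$total_reads, "reads,", x$scenario, "scenario, seed", x$seed, "\n")
  invisible(x)
}

## Static allocation checks that need no RNG.
validate_allocation <- function(design) {
  specs <- top_level_specs(design)
  abs_sum <- sum(vapply(specs, function(s)
    if (!is.null(s$ab) && s$ab$mode == "absolute") s$ab$value else 0L,
    numeric(1)))
  rel_sum <- sum(vapply(specs, function(s)
    if (!is.null(s$ab) && s$ab$mode == "relative") s$ab$value else 0,
    numeric(1)))
  n_random <- sum(vapply(specs, function(s)
    !is.null(s$ab) && s$ab$mode == "random", logical(1)))
  n_fill <- sum(vapply(specs, function(s) isTRUE(s$fill), logical(1)))
  if (rel_sum > 100 + 1e-9) {
    abort_design("relative percentages sum to ", rel_sum, " > 100")
  }
  if (n_fill > 0L && n_random > 0L) {
    abort_design("random-mode entries cannot be combined with a ",
                 "fill_remainder host (both claim the leftover reads)")
  }
  rel_quota <- round(rel_sum / 100 * design$total_reads)
  if (abs_sum + rel_quota > design$total_reads) {
    abort_design("over-allocated design: absolute (", abs_sum,
                 ") + relative (", rel_quota, ") reads exceed total_reads (",
                 design$total_reads, ")")
  }
  invisible(TRUE)
}

## Flatten design entries to a uniform top-level view:
## list of list(key, ab (abundance_spec or NULL), fill, entry).
top_level_specs <- function(design) {
  lapply(design$entries, function(e) {
    if (inherits(e, "organism_spec")) {
      list(key = e$name, ab = e$abundance, fill = e$fill_remainder, entry = e)
    } else {
      list(key = e$label, ab = e$abundance, fill = FALSE, entry = e)
    }
  })
}

#' Resolve a design to exact integer read counts per organism
#'
#' Absolute entries receive exactly their value. Relative entries are
#' rounded against their exact quotas (`value/100 * total`): plain
#' `round()` when a random or fill-remainder entry absorbs the
#' leftover (each relative then lands within half a read of its
#' requested percentage), largest-remainder corrected to the remaining
#' total when relatives must fill it exactly. Random entries
#' share the leftover via a symmetric Dirichlet draw (concentration
#' `design$random_alpha`, default 1) converted to integers by largest
#' remainder. Taxon budgets are then distributed among members with
#' [distribute_subtaxa()]. The fill-remainder host absorbs whatever is
#' left. Deterministic given `seed`.
#'
#' @param design a [sample_design()].
#' @param seed seed for the random parts; defaults to the design seed.
#' @return a `resolved_abundance` object: list with `counts` (named
#'   integer vector, one per organism, order of declaration), `total`,
#'   and `taxon` (named character vector mapping organism to taxon
#'   label, `NA` for top-level organisms).
#' @export
resolve_abundances <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "sample_design"))
  validate_allocation(design)
  specs <- top_level_specs(design)
  total <- design$total_reads

  modes <- vapply(specs, function(s)
    if (isTRUE(s$fill)) "fill" else s$ab$mode, character(1))
  counts <- integer(length(specs))

  counts[modes == "absolute"] <- vapply(
    specs[modes == "absolute"], function(s) s$ab$value, integer(1))

  rel_i <- which(modes == "relative")
  if (length(rel_i)) {
    quotas <- vapply(specs[rel_i], function(s) s$ab$value / 100 * total,
                     numeric(1))
    if (any(modes %in% c("random", "fill"))) {
      # a leftover-absorber exists: plain rounding keeps every relative
      # entry within half a read of its requested percentage
      counts[rel_i] <- as.integer(round(quotas))
    } else {
      # relatives must fill the remaining total exactly: largest-
      # remainder correction (entries stay within one read of quota)
      target <- total - sum(counts)
      if (abs(target - sum(quotas)) > length(quotas)) {
        abort_design("design does not allocate total_reads exactly: ",
                     "absolute + relative entries cover ",
                     round(sum(counts) + sum(quotas), 2), " of ", total,
                     " reads and nothing absorbs the difference")
      }
      counts[rel_i] <- largest_remainder(quotas, target)
    }
  }

  leftover <- total - sum(counts)
  rand_i <- which(modes == "random")
  if (length(rand_i)) {
    if (leftover < 0) abort_design("over-allocated design")
    shares <- with_seed(derive_seed(seed, "random-abundance"),
                        rdirichlet1(length(rand_i), design$random_alpha))
    counts[rand_i] <- largest_remainder(shares * leftover, leftover)
    leftover <- 0L
  }

  fill_i <- which(modes == "fill")
  if (length(fill_i)) {
    if (leftover < 0) {
      abort_design("over-allocated design: host remainder would be negative (",
                   leftover, ")")
    }
    counts[fill_i] <- leftover
  } else if (leftover != 0L && length(rand_i) == 0L) {
    abort_design("design does not allocate total_reads exactly: ",
                 sum(counts), " of ", total,
                 " reads assigned and no random/fill entry absorbs the rest")
  }

  # expand taxa into members
  out_counts <- integer(0)
  out_taxon <- character(0)
  for (k in seq_along(specs)) {
    e <- specs[[k]]$entry
    if (inherits(e, "organism_spec")) {
      out_counts <- c(out_counts, stats::setNames(counts[k], e$name))
      out_taxon <- c(out_taxon, stats::setNames(NA_character_, e$name))
    } else {
      member_counts <- distribute_subtaxa(
        counts[k], length(e$members), split = e$split,
        seed = derive_seed(seed, "subtaxa", e$label))
      nm <- vapply(e$members, `[[`, character(1), "name")
      out_counts <- c(out_counts, stats::setNames(member_counts, nm))
      out_taxon <- c(out_taxon, stats::setNames(rep(e$label, length(nm)), nm))
    }
  }
  if (any(out_counts < 0)) abort_design("negative resolved count")
  stopifnot(sum(out_counts) == total) # conservation invariant
  structure(list(counts = out_counts, total = total, taxon = out_taxon),
            class = "resolved_abundance")
}

#' @export
print.resolved_abundance <- function(x, ...) {
  cat("<resolved_abundance>", x$total, "reads\n")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-24s %10d  (%.3f%%)\n", names(x$counts)[i], x$counts[i],
                100 * x$counts[i] / x$total))
  }
  invisible(x)
}

#' Distribute a taxon's read budget among its members
#'
#' @param taxon_total integer reads for the whole taxon (>= 0).
#' @param n number of member organisms (>= 1).
#' @param split `"equal"`: `floor(total/n)` each with the remainder
#'   given to the first `total %% n` members in declaration order;
#'   `"random"`: symmetric Dirichlet shares converted by largest
#'   remainder.
#' @param seed seed for the random split.
#' @param alpha Dirichlet concentration for the random split.
#' @return integer vector of length `n` summing exactly to
#'   `taxon_total`.
#' @export
distribute_subtaxa <- function(taxon_total, n, split = c("equal", "random"),
                               seed = 1L, alpha = 1) {
  split <- match.arg(split)
  stopifnot(is_count(taxon_total, 0L), is_count(n, 1L))
  taxon_total <- as.integer(taxon_total); n <- as.integer(n)
  if (split == "equal") {
    base <- taxon_total %/% n
    extra <- taxon_total %% n
    counts <- rep(base, n)
    if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    return(as.integer(counts))
  }
  shares <- with_seed(seed, rdirichlet1(n, alpha))
  largest_remainder(shares * taxon_total, taxon_total)
}

#' Build a serial-dilution batch of designs
#'
#' For limit-of-detection studies: the target organism's absolute
#' abundance is set to each level while the sample total stays fixed
#' (the fill-remainder host absorbs the difference), with `replicates`
#' independent seeded replicates per level. Child seeds derive from the
#' base seed and the (level, replicate) indices, so every sample is
#' independent yet reproducible and adding levels never changes
#' existing ones.
#'
#' @param base_design a [sample_design()] containing `organism` and a
#'   fill-remainder host (or otherwise able to absorb the change).
#' @param organism name of the diluted (e.g. pathogen) organism.
#' @param levels integer vector of absolute read counts, one per
#'   dilution level.
#' @param replicates replicates per level (>= 1).
#' @return list of `sample_design` objects of length
#'   `length(levels) * replicates`, each with attributes-free fields
#'   `name` of the form `<base>_L<level>_r<replicate>` and its own
#'   derived seed.
#' @export
make_dilution_series <- function(base_design, organism, levels,
                                 replicates = 1L) {
  stopifnot(inherits(base_design, "sample_design"),
            is_count(replicates, 1L), length(levels) >= 1)
  found <- FALSE
  for (e in base_design$entries) {
    if (inherits(e, "organism_spec") && e$name == organism) found <- TRUE
  }
  if (!found) {
    abort_design("organism '", organism, "' is not a top-level entry of ",
                 "the base design")
  }
  if (any(levels > base_design$total_reads)) {
    abort_design("dilution level exceeds total_reads (",
                 base_design$total_reads, ")")
  }
  out <- vector("list", length(levels) * replicates)
  k <- 0L
  for (li in seq_along(levels)) {
    for (ri in seq_len(replicates)) {
      d <- base_design
      d$entries <- lapply(d$entries, function(e) {
        if (inherits(e, "organism_spec") && e$name == organism) {
          e$abundance <- abundance_spec("absolute", as.integer(levels[li]))
        }
        e
      })
      d$seed <- derive_seed(base_design$seed, "dilution", li, ri)
      d$replicates <- 1L
      d$name <- sprintf("%s_L%d_r%03d", base_design$name, levels[li], ri)
      validate_allocation(d)
      k <- k + 1L
      out[[k]] <- d
    }
  }
  out
}

## ---- configuration files ----------------------------------------------

read_structured_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    stop("unsupported config format '.", ext, "' (use .yaml, .yml or .json)")
  }
}

parse_abundance_field <- function(x, where) {
  if (is.null(x)) return(NULL)
  if (is.null(x$mode)) abort_design(where, ": abundance needs a 'mode'")
  abundance_spec(x$mode, x$value)
}

#' Parse a sample-design configuration file
#'
#' Accepts YAML (canonical) or JSON with the schema shown in the
#' package README, or a flat TSV shortcut with columns
#' `name`, `reference`, `mode`, `value`. Reference paths are resolved
#' relative to the config file's directory and checked for existence.
#' Defaults: scenario `environmental`, replicates 1, profile `perfect`,
#' length model (2000, 200, min 50).
#'
#' A run-parameters report written by [simulate_sample()] is itself a
#' valid config (its `design` block is used), so any run can be
#' replayed from its report alone.
#'
#' @param path path to the configuration file.
#' @param check_references verify that every referenced FASTA exists
#'   (default TRUE).
#' @return a validated [sample_design()].
#' @export
parse_design <- function(path, check_references = TRUE) {
  if (!file.exists(path)) abort_design("design file not found: ", path)
  base_dir <- dirname(normalizePath(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "reference", "mode")
    if (!all(need %in% names(tab))) {
      abort_design("TSV design needs columns: ", paste(need, collapse = ", "))
    }
    cfg <- list(organisms = lapply(seq_len(nrow(tab)), function(i) {
      list(name = tab$name[i], reference = tab$reference[i],
           abundance = list(mode = tab$mode[i],
                            value = if ("value" %in% names(tab) &&
                                        !is.na(tab$value[i])) tab$value[i]))
    }))
  } else {
    cfg <- read_structured_file(path)
    if (!is.null(cfg$design)) cfg <- cfg$design # replay from run-parameters
  }

  entries <- list()
  for (o in cfg$organisms) {
    if (is.null(o$name) || is.null(o$reference)) {
      abort_design("every organism needs 'name' and 'reference'")
    }
    ref <- o$reference
    if (!grepl("^(/|[A-Za-z]:)", ref)) ref <- file.path(base_dir, ref)
    if (check_references && !file.exists(ref)) {
      abort_design("reference file for organism '", o$name,
                   "' not found: ", ref)
    }
    entries <- c(entries, list(organism_spec(
      name = o$name, reference = ref,
      abundance = parse_abundance_field(o$abundance,
                                        paste0("organism '", o$name, "'")),
      host = isTRUE(o$host),
      fill_remainder = isTRUE(o$fill_remainder))))
  }
  for (tx in cfg$taxa) {
    if (is.null(tx$label)) abort_design("every taxon needs a 'label'")
    members <- lapply(tx$members, function(m) {
      ref <- m$reference
      if (!grepl("^(/|[A-Za-z]:)", ref)) ref <- file.path(base_dir, ref)
      if (check_references && !file.exists(ref)) {
        abort_design("reference file for taxon member '", m$name,
                     "' not found: ", ref)
      }
      taxon_member(m$name, ref)
    })
    entries <- c(entries, list(taxon_spec(
      label = tx$label,
      abundance = parse_abundance_field(tx$abundance,
                                        paste0("taxon '", tx$label, "'")),
      members = members,
      split = if (is.null(tx$split)) "equal" else tx$split)))
  }
  if (length(entries) == 0) abort_design("design contains no organisms/taxa")

  lm_cfg <- cfg$length_model
  lm <- length_model(
    mean = if (is.null(lm_cfg$mean)) 2000 else lm_cfg$mean,
    sd = if (is.null(lm_cfg$sd)) 200 else lm_cfg$sd,
    min_len = if (is.null(lm_cfg$min_len)) 50L else lm_cfg$min_len,
    max_len = lm_cfg$max_len)

  sample_design(
    entries = entries,
    total_reads = cfg$total_reads,
    scenario = if (is.null(cfg$scenario)) "environmental" else cfg$scenario,
    length_model = lm,
    profile = if (is.null(cfg$profile)) "perfect" else cfg$profile,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    replicates = if (is.null(cfg$replicates)) 1L else cfg$replicates,
    name = if (is.null(cfg$name)) {
      sub("\\.(yaml|yml|json|tsv|txt)$", "", basename(path))
    } else cfg$name,
    random_alpha = if (is.null(cfg$random_alpha)) 1 else cfg$random_alpha,
    forward_only = isTRUE(cfg$forward_only))
}

## Serialize a design back to plain lists (inverse of parse_design's
## reading; used by the run-parameters report for replayability).
design_to_list <- function(design) {
  orgs <- list(); taxa <- list()
  for (e in design$entries) {
    if (inherits(e, "organism_spec")) {
      orgs <- c(orgs, list(list(
        name = e$name, reference = e$reference,
        abundance = if (is.null(e$abundance)) NULL else
          list(mode = e$abundance$mode, value = e$abundance$value),
        host = e$host, fill_remainder = e$fill_remainder)))
    } else {
      taxa <- c(taxa, list(list(
        label = e$label,
        abundance = list(mode = e$abundance$mode, value = e$abundance$value),
        split = e$split,
        members = lapply(e$members, function(m)
          list(name = m$name, reference = m$reference)))))
    }
  }
  out <- list(
    name = design$name,
    total_reads = design$total_reads,
    scenario = design$scenario,
    seed = design$seed,
    replicates = design$replicates,
    random_alpha = design$random_alpha,
    forward_only = design$forward_only,
    length_model = list(mean = design$length_model$mean,
                        sd = design$length_model$sd,
                        min_len = design$length_model$min_len,
                        max_len = design$length_model$max_len),
    profile = if (inherits(design$profile, "error_profile"))
      design$profile$name else design$profile,
    organisms = orgs)
  if (length(taxa)) out$taxa <- taxa
  out
}

## Load every organism's reference set, keyed by organism name.
load_design_references <- function(design) {
  refs <- list()
  for (e in design$entries) {
    members <- if (inherits(e, "organism_spec")) list(e) else e$members
    for (m in members) {
      refs[[m$name]] <- read_fasta(m$reference, organism = m$name)
    }
  }
  refs
}
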