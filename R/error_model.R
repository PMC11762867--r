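## Error profiles and the de novo error-insertion algorithm.
##
## Errors are injected in a single left-to-right pass over the template
## fragment. At each template base exactly one event is drawn from
## {substitution, insertion, deletion, match} (competing risks, at most
## one event per base). Substituted bases change according to a
## transition/transversion-weighted model: the transition partner
## (A<->G, C<->T) has weight kappa against weight 1 for each of the two
## transversion partners, reflecting the chemical purine/pyrimidine
## classes. Insertions emit the template base followed by k >= 1 extra
## uniform random bases, k geometric with continuation probability
## `ins_extend`; deletions drop single bases. N is never substituted.

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_1 <- c(A = "C", G = "C", C = "A", T = "A")
TRANSVERSION_2 <- c(A = "T", G = "T", C = "G", T = "G")

#' Construct an error profile
#'
#' @param name profile label.
#' @param rate_sub,rate_ins,rate_del per-template-base event
#'   probabilities; their sum must be < 1.
#' @param kappa transition weight: a substituted base becomes its
#'   transition partner with probability `kappa / (kappa + 2)` and each
#'   transversion partner with probability `1 / (kappa + 2)`. The
#'   default 2 matches the classical ti/tv ~ 2 convention.
#' @param ins_extend geometric continuation probability in `[0, 1)` for
#'   extra inserted bases (expected insertion length is
#'   `1 / (1 - ins_extend)`).
#' @return an object of class `error_profile`.
#' @export
error_profile <- function(name, rate_sub, rate_ins, rate_del,
                          kappa = 2, ins_extend = 0.2) {
  rates <- c(rate_sub, rate_ins, rate_del)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("error rates must be finite and >= 0")
  }
  if (sum(rates) >= 1) {
    stop("rate_sub + rate_ins + rate_del must be < 1 (got ", sum(rates), ")")
  }
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (!is.finite(ins_extend) || ins_extend < 0 || ins_extend >= 1) {
    stop("ins_extend must be in [0, 1)")
  }
  structure(list(name = name, rate_sub = rate_sub, rate_ins = rate_ins,
                 rate_del = rate_del, kappa = kappa,
                 ins_extend = ins_extend),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "<error_profile> %s: sub %.4g, ins %.4g, del %.4g, kappa %.3g, ins_extend %.3g\n",
    x$name, x$rate_sub, x$rate_ins, x$rate_del, x$kappa, x$ins_extend))
  invisible(x)
}

## Preset rates are representative of recent Guppy/Dorado base-calling
## accuracies (~95% and ~99% modal), not vendor-canonical numbers; any
## study needing measured rates should supply a custom profile file.
ERROR_PRESETS <- list(
  guppy   = list(rate_sub = 0.025, rate_ins = 0.0125, rate_del = 0.0125,
                 kappa = 2, ins_extend = 0.2),
  dorado  = list(rate_sub = 0.005, rate_ins = 0.0025, rate_del = 0.0025,
                 kappa = 2, ins_extend = 0.2),
  perfect = list(rate_sub = 0, rate_ins = 0, rate_del = 0,
                 kappa = 2, ins_extend = 0)
)

#' Load an error profile from a preset name or a file
#'
#' Presets: `"guppy"` (overall error 0.05), `"dorado"` (overall error
#' 0.01) and `"perfect"` (no errors). Custom profiles are YAML or JSON
#' files with keys `name`, `rate_sub`, `rate_ins`, `rate_del` and
#' optionally `kappa`, `ins_extend`; they are validated against the
#' profile invariants.
#'
#' @param source preset name or path to a profile file.
#' @return an [error_profile()].
#' @export
load_profile <- function(source) {
  if (inherits(source, "error_profile")) return(source)
  stopifnot(is_string(source))
  if (source %in% names(ERROR_PRESETS)) {
    p <- ERROR_PRESETS[[source]]
    return(error_profile(source, p$rate_sub, p$rate_ins, p$rate_del,
                         p$kappa, p$ins_extend))
  }
  if (!file.exists(source)) {
    stop("unknown error profile preset or missing file: '", source,
         "' (presets: ", paste(names(ERROR_PRESETS), collapse = ", "), ")")
  }
  raw <- read_structured_file(source)
  need <- c("rate_sub", "rate_ins", "rate_del")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("profile file ", source, " lacks key(s): ",
         paste(missing, collapse = ", "))
  }
  error_profile(
    name = if (!is.null(raw$name)) raw$name else basename(source),
    rate_sub = raw$rate_sub, rate_ins = raw$rate_ins,
    rate_del = raw$rate_del,
    kappa = if (!is.null(raw$kappa)) raw$kappa else 2,
    ins_extend = if (!is.null(raw$ins_extend)) raw$ins_extend else 0.2)
}

#' Substitute bases under the transition/transversion model
#'
#' Each input base is replaced by its transition partner with
#' probability `kappa / (kappa + 2)` and by each transversion partner
#' with probability `1 / (kappa + 2)`; the input base is never
#' returned. Vectorised; uses the current RNG state.
#'
#' @param base character vector over `{A, C, G, T}`.
#' @param kappa transition weight (>= 0).
#' @return character vector of substituted bases, same length.
#' @export
substitute_base <- function(base, kappa = 2) {
  if (!all(base %in% c("A", "C", "G", "T"))) {
    stop("substitute_base: input must be A, C, G or T (N is never ",
         "substituted; callers must skip it)")
  }
  n <- length(base)
  is_ti <- stats::runif(n) < kappa / (kappa + 2)
  pick2 <- stats::runif(n) < 0.5 # which of the two transversion partners
  out <- ifelse(is_ti, TRANSITION_PARTNER[base],
                ifelse(pick2, TRANSVERSION_1[base], TRANSVERSION_2[base]))
  unname(out)
}

#' Apply sequencing errors to a template fragment
#'
#' Single left-to-right pass; see the module comment for the event
#' model. N bases pass through unmodified (a substitution drawn at an N
#' is re-counted as a match). Uses the current RNG state; wrap in
#' [with_seed()] / `set.seed()` for reproducibility.
#'
#' @param fragment nonempty template string over `{A, C, G, T, N}`.
#' @param profile an [error_profile()].
#' @return list with `sequence` (the mutated read) and `record`, an
#'   integer vector `c(n_sub, n_ins, n_del)` of exact event counts
#'   (`n_ins` counts inserted bases, `n_del` deleted bases).
#' @export
apply_errors <- function(fragment, profile) {
  n <- nchar(fragment)
  stopifnot(n >= 1)
  zero <- c(n_sub = 0L, n_ins = 0L, n_del = 0L)
  if (profile$rate_sub + profile$rate_ins + profile$rate_del == 0) {
    return(list(sequence = fragment, record = zero))
  }
  chars <- strsplit(fragment, "", fixed = TRUE)[[1]]
  u <- stats::runif(n)
  # 0 = sub, 1 = ins, 2 = del, 3 = match
  ev <- findInterval(u, cumsum(c(profile$rate_sub, profile$rate_ins,
                                 profile$rate_del)))
  ev[ev == 0L & chars == "N"] <- 3L
  sub_i <- which(ev == 0L)
  ins_i <- which(ev == 1L)
  del_i <- which(ev == 2L)
  if (length(sub_i)) {
    chars[sub_i] <- substitute_base(chars[sub_i], profile$kappa)
  }
  out <- chars
  n_ins_bases <- 0L
  if (length(ins_i)) {
    k <- 1L + stats::rgeom(length(ins_i), prob = 1 - profile$ins_extend)
    n_ins_bases <- sum(k)
    extra <- sample(c("A", "C", "G", "T"), n_ins_bases, replace = TRUE)
    ins_str <- vapply(split(extra, rep.int(seq_along(k), k)),
                      paste, character(1), collapse = "")
    out[ins_i] <- paste0(out[ins_i], ins_str)
  }
  if (length(del_i)) out <- out[-del_i]
  list(sequence = paste(out, collapse = ""),
       record = c(n_sub = length(sub_i), n_ins = n_ins_bases,
                  n_del = length(del_i)))
}

#' Summarize per-read error records into an error-distribution report
#'
#' @param records data frame with integer columns `n_sub`, `n_ins`,
#'   `n_del` and optionally `organism` and `template_bases` (per-read
#'   template length). Pass `template_bases` explicitly if the column
#'   is absent.
#' @param template_bases total template bases (scalar); defaults to
#'   `sum(records$template_bases)`.
#' @return list with `totals` (event counts), `rates` (per-type
#'   observed rates = events / template bases), `accuracy`
#'   (`1 - sum(events)/template_bases`, an exact bookkeeping identity,
#'   not an estimate), `template_bases`, `n_reads`, and `per_organism`
#'   (data frame, present when `records$organism` exists).
#' @export
summarize_errors <- function(records, template_bases = NULL) {
  stopifnot(all(c("n_sub", "n_ins", "n_del") %in% names(records)))
  if (is.null(template_bases)) {
    if (!"template_bases" %in% names(records)) {
      stop("template_bases must be a column of `records` or given explicitly")
    }
    template_bases <- sum(records$template_bases)
  }
  stopifnot(template_bases > 0)
  tot <- c(n_sub = sum(records$n_sub), n_ins = sum(records$n_ins),
           n_del = sum(records$n_del))
  out <- list(
    totals = tot,
    rates = tot / template_bases,
    accuracy = 1 - sum(tot) / template_bases,
    template_bases = template_bases,
    n_reads = nrow(records))
  names(out$rates) <- c("rate_sub", "rate_ins", "rate_del")
  if ("organism" %in% names(records) && "template_bases" %in% names(records)) {
    agg <- do.call(rbind, lapply(split(records, records$organism), function(d) {
      tb <- sum(d$template_bases)
      data.frame(organism = d$organism[1], n_reads = nrow(d),
                 template_bases = tb,
                 n_sub = sum(d$n_sub), n_ins = sum(d$n_ins),
                 n_del = sum(d$n_del),
                 accuracy = 1 - (sum(d$n_sub) + sum(d$n_ins) + sum(d$n_del)) / tb,
                 stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    out$per_organism <- agg
  }
  class(out) <- "error_distribution"
  out
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "<error_distribution> %d reads, %d template bases; sub %.5f, ins %.5f, del %.5f; accuracy %.4f\n",
    x$n_reads, x$template_bases, x$rates[["rate_sub"]],
    x$rates[["rate_ins"]], x$rates[["rate_del"]], x$accuracy))
  invisible(x)
}
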