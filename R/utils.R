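#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: deterministic seed derivation,
## exact integer apportionment, and small validation utilities.

#' Derive a child random seed from arbitrary components
#'
#' A stable polynomial hash over the string representation of its
#' arguments, reduced modulo 2^31 - 1 so the result is always a valid
#' (positive, 32-bit) seed for [set.seed()]. Used to give every
#' organism, replicate and dilution level its own independent,
#' reproducible random substream: reordering organisms in a design or
#' adding a replicate never changes another stream's draws.
#'
#' @param ... components (coerced to character) identifying the stream,
#'   e.g. the base seed, an organism name, a replicate index.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "organism_a", 3L)
derive_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "\x1f")
  bytes <- utf8ToInt(s)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (b in bytes) {
    h <- (h * 127 + b) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Allocates exactly `total` integer units across categories with real
#' quotas `quotas`: each category receives the floor of its quota and
#' the leftover units go to the categories with the largest fractional
#' remainders. Ties in remainders break by declaration order. This is
#' the rounding rule that guarantees the simulator's exact-total
#' abundance contract: the returned counts always sum to `total`.
#'
#' @param quotas numeric vector of nonnegative target values (need not
#'   be integers; their sum should be within 1 of `total`).
#' @param total integer number of units to allocate. Defaults to
#'   `round(sum(quotas))`.
#' @return integer vector, same length as `quotas`, summing to `total`.
#' @export
#' @examples
#' largest_remainder(c(3.34, 3.33, 3.33)) # 4 3 3
largest_remainder <- function(quotas, total = round(sum(quotas))) {
  stopifnot(is.numeric(quotas), all(quotas >= -1e-9), length(quotas) >= 1)
  total <- as.integer(round(total))
  quotas <- pmax(quotas, 0)
  base <- floor(quotas + 1e-9) # guard against 3.9999999 floor artifacts
  extra <- total - sum(base)
  if (extra < 0 || extra > length(quotas)) {
    stop("largest_remainder: total ", total, " not within one unit per ",
         "category of sum(quotas) = ", sum(quotas))
  }
  counts <- as.integer(base)
  if (extra > 0) {
    rem <- quotas - base
    take <- order(-rem, seq_along(rem))[seq_len(extra)]
    counts[take] <- counts[take] + 1L
  }
  counts
}

## with_seed: evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Symmetric Dirichlet draw (gamma normalisation).
rdirichlet1 <- function(n, alpha = 1) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, n) # degenerate safeguard for tiny alpha
  g / sum(g)
}

is_count <- function(x, min = 0L) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min &&
    abs(x - round(x)) < 1e-9
}

is_string <- function(x) length(x) == 1 && is.character(x) && !is.na(x) &&
  nzchar(x)

abort_design <- function(...) {
  stop(structure(class = c("nanomock_design_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
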