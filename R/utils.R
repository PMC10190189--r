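## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    (if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1))
  if (!ok) stop_param("'%s' must be %s", name,
                      if (open) "strictly inside (0, 1)" else "within [0, 1]")
  invisible(x)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## deterministic local RNG: run `expr` under a seed without disturbing the
## caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

## GRanges constructor with explicit seqlengths taken from a genome
granges_on <- function(genome, chrom, start, end, strand = "*", ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = rep(strand, length.out = length(chrom)),
    seqlengths = stats::setNames(genome$lengths, genome$chrom_names))
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  gr
}
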