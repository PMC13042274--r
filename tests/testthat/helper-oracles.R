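# Independent brute-force oracles used to validate the implementation.
# These deliberately recompute quantities from first principles and never
# call the package functions they check.

# exact minimal bin count by exhaustive branch-and-bound (n <= ~10)
oracle_opt_bins <- function(sizes, cap) {
  sizes <- sort(sizes[sizes <= cap], decreasing = TRUE)
  n <- length(sizes)
  if (n == 0) return(0L)
  best <- n
  recurse <- function(i, loads) {
    if (length(loads) >= best) return(invisible())
    if (i > n) { best <<- length(loads); return(invisible()) }
    for (b in seq_along(loads)) {
      if (loads[b] + sizes[i] <= cap) recurse(i + 1L, `[<-`(loads, b, loads[b] + sizes[i]))
    }
    recurse(i + 1L, c(loads, sizes[i]))
  }
  recurse(1L, numeric(0))
  best
}

# classification metrics straight from their definitions
oracle_metrics <- function(gold, pred, classes) {
  acc <- mean(gold == pred)
  prec <- vapply(classes, function(cl) {
    denom <- sum(pred == cl)
    if (denom == 0) 0 else sum(pred == cl & gold == cl) / denom
  }, numeric(1))
  rec <- vapply(classes, function(cl) {
    denom <- sum(gold == cl)
    if (denom == 0) 0 else sum(pred == cl & gold == cl) / denom
  }, numeric(1))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  n <- length(gold)
  po <- acc
  all_cl <- union(classes, unique(c(gold, pred)))
  pe <- sum(vapply(all_cl, function(cl) {
    (sum(gold == cl) / n) * (sum(pred == cl) / n)
  }, numeric(1)))
  list(accuracy = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), kappa = (po - pe) / (1 - pe))
}

# exact two-sided binomial p for discordant pairs, by direct enumeration
oracle_exact_binom_p <- function(b, c_) {
  n <- b + c_
  if (n == 0) return(1)
  m <- min(b, c_)
  min(1, 2 * sum(choose(n, 0:m)) / 2^n)
}

# chi-square(1) upper-tail probability via the error function / normal CDF
oracle_chisq1_upper <- function(x) 2 * (1 - stats::pnorm(sqrt(x)))

# a tiny benchmark shared by several tests
tiny_benchmark <- function(n_per_biome = 2, seed = 101, ...) {
  generate_benchmark(n_per_biome, seed = seed, ...)
}

make_record <- function(id = "SRS000001", ...) {
  metadata_record(id, c(...))
}
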