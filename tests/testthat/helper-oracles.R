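# Independent oracles, deliberately written with different machinery than
# the package (seqinr translation, plain nested loops, base-R arithmetic).

# Brute-force SNV enumerator: loops over every nucleotide position and
# every alternative base, translates with seqinr, and tallies unique
# non-synonymous protein variants.
oracle_snv_spectrum <- function(sequence, include_start = FALSE,
                                include_stop = FALSE) {
  nucs <- c("A", "C", "G", "T")
  s <- strsplit(sequence, "")[[1]]
  n_codon <- length(s) / 3
  translate1 <- function(codon_chars) {
    seqinr::translate(tolower(codon_chars))
  }
  last_aa <- translate1(s[(3 * n_codon - 2):(3 * n_codon)])
  events <- list()
  for (p in seq_along(s)) {
    ci <- ceiling(p / 3)
    if (!include_start && ci == 1) next
    if (!include_stop && ci == n_codon && last_aa == "*") next
    for (alt in setdiff(nucs, s[p])) {
      s2 <- s
      s2[p] <- alt
      codon <- s2[(3 * ci - 2):(3 * ci)]
      wt <- translate1(s[(3 * ci - 2):(3 * ci)])
      mut <- translate1(codon)
      if (wt == mut) next
      events[[length(events) + 1L]] <- c(paste0(wt, ci, mut),
                                         wt, mut)
    }
  }
  if (length(events) == 0L) {
    return(data.frame(variant = character(), frequency = integer(),
                      consequence = character()))
  }
  ev <- do.call(rbind, events)
  tab <- table(ev[, 1])
  out <- data.frame(variant = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  cons <- tapply(ifelse(ev[, 3] == "*" & ev[, 2] != "*", "nonsense",
                        "missense"), ev[, 1], unique)
  out$consequence <- as.character(cons[out$variant])
  out[order(out$variant), ]
}

# Total SNV event count by the same brute-force loop (synonymous included).
oracle_snv_event_count <- function(sequence, include_start = FALSE,
                                   include_stop = FALSE) {
  s <- strsplit(sequence, "")[[1]]
  n_codon <- length(s) / 3
  last_aa <- seqinr::translate(tolower(s[(3 * n_codon - 2):(3 * n_codon)]))
  count <- 0L
  for (p in seq_along(s)) {
    ci <- ceiling(p / 3)
    if (!include_start && ci == 1) next
    if (!include_stop && ci == n_codon && last_aa == "*") next
    count <- count + 3L
  }
  count
}

# Rand index between two flat partitions (plain pair counting).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}
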