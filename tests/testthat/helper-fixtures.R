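# In-code fixtures and independent oracles shared across the test files.

# Build a gene table in the internal convention: sequential CDS on one
# replicon, 0-based half-open coordinates, ranks by position.
make_genes <- function(aa, genome = "G1", replicon = genome,
                       strand = rep("+", length(aa)),
                       gene_id = sprintf("%s_g%04d", genome, seq_along(aa))) {
  n <- length(aa)
  nt <- (aa + 1L) * 3L
  gap <- 100L
  start <- cumsum(c(0L, head(nt, -1) + gap))
  data.frame(gene_id = gene_id, genome_id = genome, replicon_id = replicon,
             start = start, end = start + nt, strand = strand,
             rank = seq_len(n) - 1L, aa_length = as.integer(aa),
             product_label = "hypothetical protein", stringsAsFactors = FALSE)
}

# One domain-hit row in the read_domtblout() layout.
make_hit <- function(protein_id, profile_name, evalue = 1e-20, score = 100,
                     from = 1L, to = 100L,
                     class_map = default_profile_class_map()) {
  data.frame(protein_id = protein_id, profile_name = profile_name,
             profile_class = class_map$profile_class[
               match(profile_name, class_map$profile_name)],
             full_evalue = evalue, bitscore = score,
             env_from = as.integer(from), env_to = as.integer(to),
             passed_ga = TRUE, stringsAsFactors = FALSE)
}

make_hits <- function(...) {
  h <- rbind(...)
  h$profile_class[is.na(h$profile_class)] <- "OTHER"
  h
}

empty_hits <- function() make_hit("x", "MuF1")[0, ]

make_regions <- function(replicon, start, end, genome = replicon) {
  data.frame(genome_id = genome, replicon_id = replicon,
             start = as.integer(start), end = as.integer(end),
             length = as.integer(end - start), stringsAsFactors = FALSE)
}

make_metadata <- function(genome_id, type = "bacterium", clade = "Firmicutes",
                          phage_family = NA_character_,
                          lifestyle = NA_character_) {
  data.frame(genome_id = genome_id, type = type, clade = clade,
             phage_family = phage_family, lifestyle = lifestyle,
             stringsAsFactors = FALSE)
}

# Independent Fisher oracle: direct enumeration over the hypergeometric
# support using binomial coefficients (no dhyper).
oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  lo <- max(0L, c1 - (N - r1))
  hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1)
  }
  ps <- exp(vapply(lo:hi, logp, numeric(1)))
  pobs <- exp(logp(a))
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# Independent marker-distance oracle: exhaustive scan over all marker ranks.
oracle_marker_distance <- function(muf_rank, ranks, window) {
  best <- NA_integer_
  for (r in ranks) {
    d <- r - muf_rank
    if (d == 0L || abs(d) > window) next
    if (is.na(best) || abs(d) < abs(best) ||
        (abs(d) == abs(best) && d > best)) {
      best <- d
    }
  }
  best
}

# Pooled-variance t statistic, closed form, written independently of
# two_sample_t().
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}
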