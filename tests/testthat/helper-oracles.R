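# Independent oracles and fixture builders shared across tests.

# Weir-Cockerham variance components computed through the nested-ANOVA route
# (mean squares over allele indicators), independent of the package's closed
# a/b/c formulas.
anova_fst_oracle <- function(dosage, pops) {
  ok <- !is.na(dosage)
  d <- dosage[ok]; pops <- pops[ok]
  a1 <- as.integer(d >= 1)          # first allele copy
  a2 <- as.integer(d == 2)          # second allele copy
  y <- c(rbind(a1, a2))
  ind <- rep(seq_along(d), each = 2)
  pop <- rep(pops, each = 2)
  r <- length(unique(pop))
  n_i <- tapply(rep(1, length(d)), pops, sum)
  N <- sum(n_i)
  p_i <- tapply(y, pop, mean)
  m_ij <- tapply(y, ind, mean)
  SSP <- sum(2 * n_i * (p_i - mean(y))^2)
  SSI <- sum(2 * (m_ij - p_i[pops])^2)
  SSG <- sum((y - m_ij[ind])^2)
  MSP <- SSP / (r - 1); MSI <- SSI / (N - r); MSG <- SSG / N
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * n_c); b <- (MSI - MSG) / 2; cc <- MSG
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Write a small hand-rolled SV-VCF fixture; gts is a character matrix
# (variants x samples) of GT strings.
write_vcf_fixture <- function(path, rows, samples, gts) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(rows), function(i) {
    paste(c(rows[[i]], "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# RepeatMasker .out style fixture with the classic 3 header lines.
write_rm_fixture <- function(path, rows) {
  hdr <- c("   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
           "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left) ID",
           "")
  writeLines(c(hdr, rows), path)
  path
}

# Quadratic reference scan for interval overlap (1-based inclusive).
brute_overlap_any <- function(qs, qe, ss, se) {
  vapply(seq_along(qs), function(i) any(qs[i] <= se & ss <= qe[i]), logical(1))
}

# Tiny sorted call set builder.
make_calls <- function(chrom, pos, svtype, svlen, prefix = "c") {
  r <- sv_records(chrom = chrom, pos = pos,
                  id = paste0(prefix, seq_along(pos)),
                  svtype = svtype, svlen = svlen)
  r[order(r$chrom, r$pos), , drop = FALSE]
}
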