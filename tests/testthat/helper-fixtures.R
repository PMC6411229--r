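# Small fixtures built in code at test time.

# A valid profile matrix with reproducible random entries.
make_matrix <- function(n = 6, m = 8, seed = 42, prefix = "PROT") {
  set.seed(seed)
  vals <- matrix(rnorm(n * m), n, m,
                 dimnames = list(sprintf("%s%03d_S%d", prefix, seq_len(n),
                                         seq_len(n) * 10),
                                 sprintf("state%02d", seq_len(m))))
  suppressWarnings(phospho_matrix(vals))
}

# Write an intensity TSV from a body of pre-formatted lines.
write_matrix_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

write_ksa_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c("kinase\tsubstrate\tsite",
               if (nrow(df) > 0)
                 paste(df$kinase, df$substrate, df$site, sep = "\t")),
             path)
  path
}

write_static_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c("kinase\tsite_id\tscore",
               if (nrow(df) > 0)
                 paste(df$kinase, df$site_id, df$score, sep = "\t")),
             path)
  path
}

# A tiny scoring instance: network from a synthetic matrix plus a
# hand-specified annotation over its sites.
make_instance <- function(n_sites = 6, m = 10, n_kinases = 2,
                          subs_per_kinase = 3, seed = 1) {
  mat <- make_matrix(n = n_sites, m = m, seed = seed)
  net <- suppressWarnings(build_cophos_network(mat))
  set.seed(seed + 1000)
  kin <- sprintf("K%d", seq_len(n_kinases))
  ksa_df <- do.call(rbind, lapply(kin, function(k) {
    data.frame(kinase = k,
               site_id = sample(net$sites, min(subs_per_kinase,
                                               length(net$sites))),
               stringsAsFactors = FALSE)
  }))
  ksa <- suppressMessages(suppressWarnings(
    ksa_annotation(ksa_df$kinase, ksa_df$site_id)))
  list(matrix = mat, network = net, ksa = ksa)
}
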