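# Shared fixture helpers.

fixture_path <- function(...) {
  system.file("extdata", ..., package = "idrctd", mustWork = TRUE)
}

fixture_region <- function(name) {
  cfg <- read.csv(fixture_path("ctd_regions.csv"))
  i <- match(name, cfg$name)
  read_fasta_region(fixture_path(cfg$source[i]), cfg$start[i], cfg$end[i],
                    name = name, record = cfg$record[i])
}

# independent oracle for the delta_max convention: exhaustive maximum of
# the blob delta over all arrangements in which the np positive and nm
# negative charges each form one contiguous block, enumerated by the two
# block start positions
block_layout_delta_max <- function(np, nm, L, windows = c(5L, 6L)) {
  best <- rep(-Inf, length(windows))
  for (sp in seq_len(L - np + 1L)) {
    p_idx <- sp:(sp + np - 1L)
    for (sm in seq_len(L - nm + 1L)) {
      m_idx <- sm:(sm + nm - 1L)
      if (length(intersect(p_idx, m_idx))) next
      q <- integer(L)
      q[p_idx] <- 1L
      q[m_idx] <- -1L
      d <- vapply(windows, idrctd:::blob_delta, 0, q = q)
      best <- pmax(best, d)
    }
  }
  best
}

# random canonical amino-acid string
random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
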