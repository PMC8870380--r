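# shared builders for constructed (non-simulated) mini-cohorts

# one variant record as used by build_background_null()/test_presence()
mk_variant <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T") {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

# allele-count rows for one variant across samples; freqs set via alt of depth
mk_counts <- function(sample_ids, alt_counts, depths,
                      chrom = "chr1", pos = 100L, ref = "A", alt = "T") {
  tibble::tibble(sample_id = sample_ids, chrom = chrom, pos = pos,
                 ref = ref, alt = alt,
                 ref_count = as.integer(depths - alt_counts),
                 alt_count = as.integer(alt_counts))
}

# sample table: one patient per sample unless patient_ids given
mk_samples <- function(sample_ids, patient_ids = sample_ids,
                       months = rep(0L, length(sample_ids)),
                       stage = NULL) {
  if (is.null(stage)) stage <- ifelse(months > 0, "MGUS", "MM")
  tibble::tibble(sample_id = sample_ids, patient_id = patient_ids,
                 stage = stage, months_before_mm = as.integer(months),
                 seq_mode = "standard")
}

# a fully specified variant call row for filter tests
mk_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    depth = 500L, alt_count = 50L,
                    consequence = "missense", classification = "pathogenic",
                    gene = "KRAS") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 depth = as.integer(depth), alt_count = as.integer(alt_count),
                 vaf = alt_count / depth, consequence = consequence,
                 classification = classification, gene = gene)
}

# random plausible call table for property tests
random_calls <- function(n, seed) {
  withr::with_seed(seed, {
    depth <- sample(1:200, n, replace = TRUE)
    alt_count <- rbinom(n, depth, runif(n, 0, 0.3))
    tibble::tibble(
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e6L, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = NA_character_,
      depth = depth, alt_count = alt_count,
      vaf = ifelse(depth > 0, alt_count / depth, 0),
      consequence = sample(c("missense", "stop_gain", "frameshift",
                             "splice_site", "synonymous", "other"),
                           n, replace = TRUE),
      classification = sample(c("pathogenic", "likely_pathogenic", "VUS",
                                "benign", "likely_benign", NA),
                              n, replace = TRUE),
      gene = sample(c("KRAS", "NRAS", "TP53", "NOTAGENE", "DNMT3A"),
                    n, replace = TRUE)
    ) -> calls
    calls$alt <- vapply(calls$ref,
                        function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                        character(1))
    calls
  })
}

# independent one-predicate-at-a-time re-implementation of the filter
naive_filter <- function(calls, panel, cfg) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls$classification[i]
    if (is.na(cl)) cl <- "unclassified"
    ok <- calls$depth[i] > cfg$min_coverage_exclusive
    ok <- ok && calls$vaf[i] >= cfg$min_vaf
    ok <- ok && calls$consequence[i] %in% cfg$kept_consequences
    ok <- ok && cl %in% cfg$kept_classifications
    if (cfg$restrict_to_panel) {
      ok <- ok && (mmbacktrack::normalize_gene_symbols(calls$gene[i]) %in%
                     panel$genes)
    }
    keep[i] <- ok
  }
  calls[keep, ]
}
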