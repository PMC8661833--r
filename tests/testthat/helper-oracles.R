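# Independent brute-force oracles, deliberately written as plain nested
# loops over samples x genes x variants so they share no code path with the
# package's vectorised encoders. Variant tables are handled as parallel
# column vectors for speed; the counting logic itself stays naive.

# frequency class by direct threshold comparison (methods closure)
oracle_class <- function(maf, is_indel, carriers) {
  if (is.na(maf)) {
    if (!is_indel) return("ultra_rare")
    return(if (carriers == 1) "ultra_rare" else "discarded")
  }
  if (maf < 0.001) "ultra_rare"
  else if (maf < 0.01) "rare"
  else if (maf < 0.05) "low_frequency"
  else "common"
}

# per-cell recount of a collapsed representation; vv is a base list of
# column vectors already restricted to the feature's class and gene
oracle_collapsed_cell <- function(vv, sample, model) {
  count <- 0
  for (i in seq_along(vv$sample_id)) {
    if (vv$sample_id[i] != sample || !vv$protein_impacting[i]) next
    if (model == "AR" && vv$zygosity[i] %in% c("homozygous_alt", "hemizygous")) {
      count <- count + 2
    } else {
      count <- count + 1
    }
  }
  need <- if (model == "AR") 2 else 1
  as.integer(count >= need)
}

# per-cell recount of a common combination feature: 1 iff every member
# variant is carried (AD/XL: any zygosity; AR: homozygous or hemizygous)
oracle_common_cell <- function(vv, sample, members, model) {
  for (k in members) {
    ok <- FALSE
    for (i in seq_along(vv$sample_id)) {
      if (vv$sample_id[i] != sample || !vv$protein_impacting[i]) next
      if (vv$key[i] != k) next
      if (model == "AR") {
        if (vv$zygosity[i] %in% c("homozygous_alt", "hemizygous")) ok <- TRUE
      } else ok <- TRUE
    }
    if (!ok) return(0L)
  }
  1L
}

# per-cell recount of a common "absence" feature
oracle_absence_cell <- function(vv, sample, model) {
  for (i in seq_along(vv$sample_id)) {
    if (vv$sample_id[i] != sample || !vv$protein_impacting[i]) next
    if (model == "AR") {
      if (vv$zygosity[i] %in% c("homozygous_alt", "hemizygous")) return(0L)
    } else return(0L)
  }
  1L
}

# full recount of every cell of every representation; the class of every
# variant is re-derived independently (thresholds + cohort carrier counts)
oracle_check_representations <- function(reps, variants) {
  keys <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  carriers <- table(keys[!duplicated(paste(variants$sample_id, keys))])
  v_class <- vapply(seq_len(nrow(variants)), function(i) {
    oracle_class(variants$ref_maf[i],
                 nchar(variants$ref[i]) != nchar(variants$alt[i]),
                 as.integer(carriers[[keys[i]]]))
  }, "")
  cols <- list(sample_id = variants$sample_id, gene = variants$gene,
               protein_impacting = variants$protein_impacting,
               zygosity = variants$zygosity, key = keys)
  slice_cols <- function(keep) lapply(cols, function(x) x[keep])
  for (r in reps) {
    model <- if (grepl("_X$", r$name)) "XL" else sub("^.*_", "", r$name)
    for (j in seq_len(ncol(r$matrix))) {
      f <- r$features[j, ]
      vv <- slice_cols(v_class == f$class & cols$gene == f$gene)
      for (s in r$samples) {
        expected <- if (f$class == "common") {
          if (identical(f$members, "absence")) {
            oracle_absence_cell(vv, s, model)
          } else {
            oracle_common_cell(vv, s,
                               strsplit(f$members, "+", fixed = TRUE)[[1]], model)
          }
        } else {
          oracle_collapsed_cell(vv, s, model)
        }
        if (expected != r$matrix[s, f$feature_id]) {
          return(sprintf("mismatch at %s / %s / %s: oracle %d, matrix %d",
                         r$name, f$feature_id, s, expected,
                         r$matrix[s, f$feature_id]))
        }
      }
    }
  }
  TRUE
}

# independent single-pass evaluation of the IPGS formula
oracle_ipgs <- function(comp_row, f_lf, f_r, f_ur) {
  (comp_row$n_C_s - comp_row$n_C_m) +
    f_lf * (comp_row$n_LF_s - comp_row$n_LF_m) +
    f_r * (comp_row$n_R_s - comp_row$n_R_m) +
    f_ur * (comp_row$n_UR_s - comp_row$n_UR_m)
}

# naive O(n^2) mean silhouette for 1-D points and two fixed clusters
oracle_silhouette <- function(x, g) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(g == g[i]); own <- own[own != i]
    other <- which(g != g[i])
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(abs(x[i] - x[own]))
    b <- mean(abs(x[i] - x[other]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# small planted-effect cohort shared by several tests
small_sim <- function(n = 300, seed = 11, ...) {
  simulate_cohort(simulation_config(n_samples = n, n_genes_autosomal = 20L,
                                    n_genes_x = 4L, seed = seed, ...))
}
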