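# Internal error helper: all package errors carry a condition class so
# callers (and the CLI) can distinguish config from data problems.
tsStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ts_error")))
}

# Deterministic local RNG scope: runs expr with the given seed without
# disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# 27 human tissue names used by the synthetic generator (target first
# tissue alphabetically irrelevant; profiles order tissues lexicographically).
compendiumTissues <- function(n = 27L, target = "kidney") {
  pool <- c("adipose_tissue", "adrenal_gland", "appendix", "bone_marrow",
            "brain", "colon", "duodenum", "endometrium", "esophagus",
            "gallbladder", "heart", "kidney", "liver", "lung", "lymph_node",
            "ovary", "pancreas", "placenta", "prostate", "salivary_gland",
            "skeletal_muscle", "skin", "small_intestine", "spleen",
            "stomach", "testis", "thyroid")
  pool <- unique(c(target, pool))
  if (n <= length(pool)) return(sort(pool[seq_len(n)]))
  extra <- sprintf("tissue_%02d", seq_len(n - length(pool)))
  sort(c(pool, extra))
}
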