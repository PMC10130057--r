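# Shared fixtures, built in code.

# A tidy steady-state series with constant effluent values.
constant_series <- function(effluent, n = 3) {
  do.call(rbind, lapply(names(effluent), function(sp) {
    data.frame(time_d = seq_len(n), species = sp,
               value = effluent[[sp]], unit = "mg N/L")
  }))
}

# Small CDS table: three genomes, known gene symbols.
toy_cds <- function() {
  data.frame(
    cds_id = paste0("c", 1:6),
    genome_id = c("G1", "G1", "G1", "G2", "G2", "unbinned"),
    gene_symbol = c("pmoC", "pmoA", "pmoB", "narG", "napA", "hypo1"),
    length = c(100, 200, 300, 400, 500, 600),
    strand = c("+", "+", "-", "+", "-", "+")
  )
}

toy_function_map <- function() {
  function_map(
    complexes = list(pmoCAB = c("pmoC", "pmoA", "pmoB"),
                     nar = "narG", nap = "napA"),
    reactions = list(methane_oxidation = "pmoCAB",
                     nitrate_reduction = c("nar", "nap")),
    pathways = list(aom = "methane_oxidation",
                    denitrification = "nitrate_reduction",
                    n_cycle = c("methane_oxidation", "nitrate_reduction"))
  )
}

# Independent brute-force two-sided Mann-Whitney oracle: enumerate every
# assignment of pooled midranks to group x.
bruteforce_mwu <- function(x, y) {
  n_x <- length(x)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n_x * (n_x + 1) / 2
  u_obs <- u_of(seq_len(n_x))
  us <- apply(utils::combn(length(r), n_x), 2, u_of)
  eps <- 1e-9
  list(U = u_obs,
       p = min(1, 2 * min(mean(us <= u_obs + eps),
                          mean(us >= u_obs - eps))))
}
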