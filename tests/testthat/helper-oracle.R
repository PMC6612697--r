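# Independent brute-force gamma oracle: for every included reference point,
# minimize Gamma over ALL evaluated samples with no radius cap, using plain
# position arithmetic. Deliberately shares no code with the engine.
brute_gamma_map <- function(ref, evg, dd_pct, dta_mm, ldt_pct = 5) {
  rx <- ref$origin[1] + (seq_len(nrow(ref$values)) - 1) * ref$spacing[1]
  ry <- ref$origin[2] + (seq_len(ncol(ref$values)) - 1) * ref$spacing[2]
  ex <- evg$origin[1] + (seq_len(nrow(evg$values)) - 1) * evg$spacing[1]
  ey <- evg$origin[2] + (seq_len(ncol(evg$values)) - 1) * evg$spacing[2]
  norm <- max(ref$values)
  ddab <- dd_pct * norm / 100
  thr <- ldt_pct * norm / 100
  g <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  for (j in seq_len(ncol(ref$values))) {
    for (i in seq_len(nrow(ref$values))) {
      if (ref$values[i, j] < thr) next
      d2 <- outer((ex - rx[i])^2, (ey - ry[j])^2, `+`)
      G2 <- ((evg$values - ref$values[i, j]) / ddab)^2 + d2 / dta_mm^2
      g[i, j] <- sqrt(min(G2))
    }
  }
  g
}
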