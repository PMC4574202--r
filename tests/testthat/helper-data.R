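# small fixture builders used across test files

toyVials <- function(values_by_cell) {
  # values_by_cell: named list "line|sex" -> numeric vials
  do.call(rbind, lapply(names(values_by_cell), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    v <- values_by_cell[[k]]
    data.frame(line = p[1], sex = p[2], replicate = seq_along(v),
               adjusted_ul = v, stringsAsFactors = FALSE)
  }))
}

quickSim <- function(seed, ...) {
  cfg <- simulationConfig(seed = seed, ...)
  sim <- simulatePhenotypes(cfg)
  adj <- adjustConsumption(sim$vials, sim$controls)
  list(cfg = cfg, sim = sim, adj = adj)
}

# balanced gaussian panel with known components, bypassing the generator
# (used where the test's subject IS the generator-independent fitter)
gaussPanel <- function(seed, L = 30, n = 4, vL = 8, vS = 2, vE = 12,
                       sexeff = 1) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(L))
  eL <- rnorm(L, 0, sqrt(vL))
  eSL <- matrix(rnorm(2 * L, 0, sqrt(vS)), L, 2)
  out <- expand.grid(replicate = seq_len(n), sex = c("F", "M"),
                     line = lines, stringsAsFactors = FALSE)
  li <- match(out$line, lines)
  si <- match(out$sex, c("F", "M"))
  out$adjusted_ul <- 10 + ifelse(out$sex == "F", sexeff / 2, -sexeff / 2) +
    eL[li] + eSL[cbind(li, si)] + rnorm(nrow(out), 0, sqrt(vE))
  out
}
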