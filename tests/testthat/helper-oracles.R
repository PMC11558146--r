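# Brute-force L1 distance, kept deliberately naive as the oracle.
l1_loop <- function(x, w) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - w[i])
  s
}

# Small hand-built CRN: A + B -> C at rate k.
abc_crn <- function(k = 0.09, a0 = 10, b0 = 10) {
  crn(
    species = data.frame(name = c("A", "B", "C"), role = c("A", "B", "C"),
                         initial = c(a0, b0, 0), module = "test",
                         stringsAsFactors = FALSE),
    reactions = data.frame(r1 = "A", r2 = "B", p1 = "C",
                           p2 = NA_character_, p3 = NA_character_,
                           rate = k, module = "test",
                           stringsAsFactors = FALSE)
  )
}

# Cooperative annihilation subsystem: S1 + ANH <-> I; S2 + I -> 2 W.
anh_crn <- function(s1 = 10, s2 = 8, gate = 12, kf = 0.09, kr = 0.1) {
  crn(
    species = data.frame(
      name = c("S1", "S2", "ANH", "I", "W"),
      role = c("S", "S", "ANH", "AI", "WASTE"),
      initial = c(s1, s2, gate, 0, 0), module = "test",
      stringsAsFactors = FALSE),
    reactions = data.frame(
      r1 = c("S1", "I", "S2"),
      r2 = c("ANH", NA, "I"),
      p1 = c("I", "S1", "W"),
      p2 = c(NA, "ANH", "W"),
      p3 = NA_character_,
      rate = c(kf, kr, kf), module = "test",
      stringsAsFactors = FALSE)
  )
}

# Trained fit + scaled sample matrix shared by end-to-end tests.
make_fit <- function(n_prototypes = 3, seed = 7, n = c(80, 80)) {
  d <- gen_morphology_like(n = n, seed = seed)
  x <- as.matrix(d[, -(1:2)])
  list(fit = lvq(x, d$label, n_prototypes = n_prototypes, seed = seed),
       x = x, y = d$label)
}

# Conservation-law drift of a simulated trajectory: max relative deviation
# of every law over all time points.
max_law_drift <- function(net, sim) {
  laws <- conservation_laws(net)
  if (ncol(laws) == 0L) return(0)
  vals <- sim$conc[, rownames(laws), drop = FALSE] %*% laws
  ref <- vals[1L, ]
  scale <- pmax(abs(ref), 1e-6)
  max(abs(sweep(vals, 2L, ref, "-")) / rep(scale, each = nrow(vals)))
}
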