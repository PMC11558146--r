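## Species naming grammar: ROLE[i=..,j=..,k=..,l=..] with keys always in
## the order i, j, k, l and only the keys the role carries.
sp_name <- function(role, i = NULL, j = NULL, k = NULL, l = NULL) {
  keys <- c(i = i, j = j, k = k, l = l)
  if (!length(keys)) return(role)
  paste0(role, "[", paste(names(keys), keys, sep = "=", collapse = ","), "]")
}

## Mutable accumulator for building fragments without repeated rbind.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$sp <- list()
  env$rx <- list()
  env
}

add_species <- function(b, name, role, initial, module) {
  b$sp[[length(b$sp) + 1L]] <- list(name = name, role = role,
                                    initial = initial, module = module)
  invisible(b)
}

add_reaction <- function(b, r1, r2, products, rate, module) {
  products <- c(products, rep(NA_character_, 3L - length(products)))
  b$rx[[length(b$rx) + 1L]] <- list(
    r1 = r1, r2 = if (is.null(r2)) NA_character_ else r2,
    p1 = products[1L], p2 = products[2L], p3 = products[3L],
    rate = rate, module = module)
  invisible(b)
}

builder_crn <- function(b, rates, metadata = list()) {
  todf <- function(lst, template) {
    if (!length(lst)) return(template)
    df <- do.call(rbind, lapply(lst, function(row)
      as.data.frame(row, stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    df
  }
  crn(todf(b$sp, empty_species()), todf(b$rx, empty_reactions()),
      rates, metadata)
}

check_ab <- function(a, b) {
  b <- as.matrix(b)
  if (any(a < 0)) stop("negative input concentration", call. = FALSE)
  if (length(a) != nrow(b)) {
    stop("weight matrix must have one row per input feature", call. = FALSE)
  }
  b
}

#' Input activation fragment
#'
#' Catalytic release of the input and weight strands. The activation factor
#' `IN[i]` reversibly displaces the input strand `X[i,j]` out of the input
#' substrate `XSUB[i,j]` and the (positive or negative) weight strand
#' `W[i,j]`/`NW[i,j]` out of the weight substrate `WSUB[i,j]`, leaving a
#' common intermediate `INT[i]`; the fuel strand `XFUEL[i]` regenerates
#' `IN[i]` from the intermediate, releasing an inert toehold-free waste
#' duplex — that step is irreversible and drives the catalytic cycle to full
#' substrate conversion. All steps run at the fast toehold-G binding rate
#' (both directions for the reversible steps). Initial concentrations follow
#' the recipe: `[IN[i]] = [XSUB[i,j]] = a_i`, `[WSUB[i,j]] = |b_ij|`, and
#' `[XFUEL[i]] = 200% * sum_j(a_i + |b_ij|)`.
#'
#' @param a numeric vector of scaled input concentrations a_i (nM).
#' @param b signed weight matrix b_ij (nM), one row per feature i, one column
#'   per prototype j.
#' @param rates a [rate_table()].
#' @return a `crn` fragment.
#' @export
build_input_activation <- function(a, b, rates = rate_table()) {
  b <- check_ab(a, b)
  g <- bind_nM(rates, "G")
  bl <- new_builder()
  mod <- "input_activation"
  for (i in seq_along(a)) {
    fuel <- 2 * sum(a[i] + abs(b[i, ]))
    add_species(bl, sp_name("IN", i = i), "IN", a[i], mod)
    add_species(bl, sp_name("XFUEL", i = i), "XFUEL", fuel, mod)
    add_species(bl, sp_name("INT", i = i), "INT", 0, mod)
    add_species(bl, sp_name("FW", i = i), "FW", 0, mod)
    for (j in seq_len(ncol(b))) {
      w_role <- if (b[i, j] >= 0) "W" else "NW"
      xsub <- sp_name("XSUB", i = i, j = j)
      wsub <- sp_name("WSUB", i = i, j = j)
      x_ij <- sp_name("X", i = i, j = j)
      w_ij <- sp_name(w_role, i = i, j = j)
      in_i <- sp_name("IN", i = i)
      int_i <- sp_name("INT", i = i)
      add_species(bl, xsub, "XSUB", a[i], mod)
      add_species(bl, wsub, "WSUB", abs(b[i, j]), mod)
      add_species(bl, x_ij, "X", 0, mod)
      add_species(bl, w_ij, w_role, 0, mod)
      add_reaction(bl, in_i, xsub, c(x_ij, int_i), g, mod)
      add_reaction(bl, x_ij, int_i, c(in_i, xsub), g, mod)
      add_reaction(bl, in_i, wsub, c(w_ij, int_i), g, mod)
      add_reaction(bl, w_ij, int_i, c(in_i, wsub), g, mod)
    }
    ## fuel step: the displaced fuel waste FW is an inert toehold-free
    ## duplex, so regeneration of IN is irreversible and drives the cycle
    ## to full substrate conversion
    add_reaction(bl, sp_name("INT", i = i), sp_name("XFUEL", i = i),
                 c(sp_name("IN", i = i), sp_name("FW", i = i)), g, mod)
  }
  builder_crn(bl, rates)
}

#' Subtraction-annihilation fragment
#'
#' Cooperative-hybridization annihilation of matched input/weight strand
#' pairs: `X[i,j]` or `W[i,j]` binds one toehold of the subtraction gate
#' `SG[i,j]` (reversibly, unbinding at the toehold-G unbinding rate); the
#' complementary strand then binds the opposite toehold and irreversibly
#' disassembles the gate into two inert waste strands. The pair is consumed
#' one-for-one until the minority species is exhausted, leaving
#' `|a_i - b_ij|` worth of the majority strand. Negative-weight channels emit
#' no gate: the `NW[i,j]` strand does not match the gate's branch-migration
#' domain, so the corresponding `X[i,j]` is left entirely unconsumed.
#'
#' Gate concentration follows the recipe `120% * max(0, min(a_i, b_ij))`
#' unless `sg` is supplied (module fixtures use a fixed `120% * range`).
#'
#' @inheritParams build_input_activation
#' @param sg optional fixed gate concentration (nM) applied to every
#'   positive-weight channel.
#' @return a `crn` fragment.
#' @export
build_subtraction_annihilation <- function(a, b, rates = rate_table(),
                                           sg = NULL) {
  b <- check_ab(a, b)
  g <- bind_nM(rates, "G")
  gu <- unname(rates$unbind[["G"]])
  bl <- new_builder()
  mod <- "subtraction_annihilation"
  add_species(bl, "WASTE", "WASTE", 0, mod)
  for (i in seq_along(a)) {
    for (j in seq_len(ncol(b))) {
      if (b[i, j] < 0) next
      x_ij <- sp_name("X", i = i, j = j)
      w_ij <- sp_name("W", i = i, j = j)
      sg_ij <- sp_name("SG", i = i, j = j)
      sgix <- sp_name("SGIX", i = i, j = j)
      sgiw <- sp_name("SGIW", i = i, j = j)
      conc <- if (is.null(sg)) 1.2 * max(0, min(a[i], b[i, j])) else sg
      add_species(bl, x_ij, "X", 0, mod)
      add_species(bl, w_ij, "W", 0, mod)
      add_species(bl, sg_ij, "SG", conc, mod)
      add_species(bl, sgix, "SGIX", 0, mod)
      add_species(bl, sgiw, "SGIW", 0, mod)
      add_reaction(bl, x_ij, sg_ij, sgix, g, mod)
      add_reaction(bl, sgix, NULL, c(x_ij, sg_ij), gu, mod)
      add_reaction(bl, w_ij, sg_ij, sgiw, g, mod)
      add_reaction(bl, sgiw, NULL, c(w_ij, sg_ij), gu, mod)
      add_reaction(bl, w_ij, sgix, c("WASTE", "WASTE"), g, mod)
      add_reaction(bl, x_ij, sgiw, c("WASTE", "WASTE"), g, mod)
    }
  }
  builder_crn(bl, rates)
}

#' Absolute-value summation fragment
#'
#' Converts the strands surviving annihilation into the distance factor
#' `D[j]`. The residual `X[i,j]` (or `W[i,j]`/`NW[i,j]`) reversibly displaces
#' the input-sum strand `XS[j]` (weight-sum strand `WS[j]`) out of its
#' summation gate `SUMX[i,j]` (`SUMW[i,j]`) through the slow toehold H
#' (bimolecular in both directions at the H binding rate); the sum strands
#' are then irreversibly converted by the total-summation gate `SUM[j]`
#' through toehold T into `D[j]`, which pulls the reversible first step to
#' completion. The resulting `[D[j]]` approaches the Manhattan distance
#' `sum_i |a_i - b_ij|`.
#'
#' Gate concentrations follow the recipe (`120% * |a_i - b_ij|` per channel
#' and `120% * sum_i |a_i - b_ij|` for the total gate) unless fixed values
#' are supplied.
#'
#' @inheritParams build_input_activation
#' @param sumx,sumw,sum_gate optional fixed gate concentrations (nM).
#' @return a `crn` fragment.
#' @export
build_abs_summation <- function(a, b, rates = rate_table(),
                                sumx = NULL, sumw = NULL, sum_gate = NULL) {
  b <- check_ab(a, b)
  h <- bind_nM(rates, "H")
  tt <- bind_nM(rates, "T")
  bl <- new_builder()
  mod <- "abs_summation"
  add_species(bl, "WASTE", "WASTE", 0, mod)
  for (j in seq_len(ncol(b))) {
    xs_j <- sp_name("XS", j = j)
    ws_j <- sp_name("WS", j = j)
    sum_j <- sp_name("SUM", j = j)
    d_j <- sp_name("D", j = j)
    conc_sum <- if (is.null(sum_gate)) 1.2 * sum(abs(a - b[, j])) else
      sum_gate
    add_species(bl, xs_j, "XS", 0, mod)
    add_species(bl, ws_j, "WS", 0, mod)
    add_species(bl, sum_j, "SUM", conc_sum, mod)
    add_species(bl, d_j, "D", 0, mod)
    for (i in seq_along(a)) {
      w_role <- if (b[i, j] >= 0) "W" else "NW"
      x_ij <- sp_name("X", i = i, j = j)
      w_ij <- sp_name(w_role, i = i, j = j)
      sumx_ij <- sp_name("SUMX", i = i, j = j)
      sumw_ij <- sp_name("SUMW", i = i, j = j)
      sxw_ij <- sp_name("SXW", i = i, j = j)
      sww_ij <- sp_name("SWW", i = i, j = j)
      cx <- if (is.null(sumx)) 1.2 * abs(a[i] - b[i, j]) else sumx
      cw <- if (is.null(sumw)) 1.2 * abs(a[i] - b[i, j]) else sumw
      add_species(bl, x_ij, "X", 0, mod)
      add_species(bl, w_ij, w_role, 0, mod)
      add_species(bl, sumx_ij, "SUMX", cx, mod)
      add_species(bl, sumw_ij, "SUMW", cw, mod)
      add_species(bl, sxw_ij, "SXW", 0, mod)
      add_species(bl, sww_ij, "SWW", 0, mod)
      add_reaction(bl, x_ij, sumx_ij, c(xs_j, sxw_ij), h, mod)
      add_reaction(bl, xs_j, sxw_ij, c(x_ij, sumx_ij), h, mod)
      add_reaction(bl, w_ij, sumw_ij, c(ws_j, sww_ij), h, mod)
      add_reaction(bl, ws_j, sww_ij, c(w_ij, sumw_ij), h, mod)
    }
    add_reaction(bl, xs_j, sum_j, c(d_j, "WASTE"), tt, mod)
    add_reaction(bl, ws_j, sum_j, c(d_j, "WASTE"), tt, mod)
  }
  builder_crn(bl, rates)
}

#' Loser-take-all competitive fragment
#'
#' Implements the competitive layer: signal reversal (`D[j]` is consumed by
#' the reversal gates `SRG[j,k]`, one per k != j, splitting its concentration
#' evenly into the reversal factors `SF[j,k]`), reverse summation (`SF[j,k]`
#' plus gate `RSG[k]` releases the reverse signal `S[k]`, so at ideal
#' completion `S_k = (sum_j d_j - d_k) / (n - 1)` and the smallest distance
#' becomes the largest reverse signal), and pairwise annihilation of the
#' reverse signals through cooperative gates `ANH[k,j]` until only the
#' largest survives. Reversal and reverse summation run irreversibly at the
#' fast toehold-G rate; annihilation follows the same cooperative kinetics as
#' the subtraction gate.
#'
#' @param d_ideal numeric vector of ideal distance-factor concentrations d_j
#'   (nM), length >= 2; sets the gate recipe (`SRG`/`RSG` at `100% * max d`,
#'   `ANH` at `120% * max s`).
#' @param rates a [rate_table()].
#' @param d_init optional initial `D[j]` concentrations (nM) for running the
#'   fragment standalone; in a compiled network `D[j]` starts at 0 and is
#'   produced upstream.
#' @param srg,rsg,anh optional fixed gate concentrations (nM) overriding the
#'   recipe.
#' @return a `crn` fragment.
#' @export
build_loser_take_all <- function(d_ideal, rates = rate_table(),
                                 d_init = NULL, srg = NULL, rsg = NULL,
                                 anh = NULL) {
  n <- length(d_ideal)
  if (n < 2L) stop("loser-take-all needs at least two competitors",
                   call. = FALSE)
  s_ideal <- (sum(d_ideal) - d_ideal) / (n - 1)
  if (is.null(srg)) srg <- max(d_ideal)
  if (is.null(rsg)) rsg <- max(d_ideal)
  if (is.null(anh)) anh <- 1.2 * max(s_ideal)
  g <- bind_nM(rates, "G")
  gu <- unname(rates$unbind[["G"]])
  bl <- new_builder()
  for (j in seq_len(n)) {
    add_species(bl, sp_name("D", j = j), "D",
                if (is.null(d_init)) 0 else d_init[j], "signal_reversal")
    add_species(bl, sp_name("S", k = j), "S", 0, "reverse_summation")
    add_species(bl, sp_name("RSG", k = j), "RSG", rsg, "reverse_summation")
  }
  add_species(bl, "WASTE", "WASTE", 0, "annihilation")
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == j) next
      srg_jk <- sp_name("SRG", j = j, k = k)
      sf_jk <- sp_name("SF", j = j, k = k)
      add_species(bl, srg_jk, "SRG", srg, "signal_reversal")
      add_species(bl, sf_jk, "SF", 0, "signal_reversal")
      add_reaction(bl, sp_name("D", j = j), srg_jk, c(sf_jk, "WASTE"), g,
                   "signal_reversal")
      add_reaction(bl, sf_jk, sp_name("RSG", k = k),
                   c(sp_name("S", k = k), "WASTE"), g, "reverse_summation")
    }
  }
  for (p in seq_len(n - 1L)) {
    for (q in seq((p + 1L), n)) {
      anh_pq <- sp_name("ANH", k = p, j = q)
      ai_pq <- sp_name("AI", k = p, j = q)   # S_p bound to the gate
      ai_qp <- sp_name("AI", k = q, j = p)   # S_q bound to the gate
      s_p <- sp_name("S", k = p)
      s_q <- sp_name("S", k = q)
      add_species(bl, anh_pq, "ANH", anh, "annihilation")
      add_species(bl, ai_pq, "AI", 0, "annihilation")
      add_species(bl, ai_qp, "AI", 0, "annihilation")
      add_reaction(bl, s_p, anh_pq, ai_pq, g, "annihilation")
      add_reaction(bl, ai_pq, NULL, c(s_p, anh_pq), gu, "annihilation")
      add_reaction(bl, s_q, ai_pq, c("WASTE", "WASTE"), g, "annihilation")
      add_reaction(bl, s_q, anh_pq, ai_qp, g, "annihilation")
      add_reaction(bl, ai_qp, NULL, c(s_q, anh_pq), gu, "annihilation")
      add_reaction(bl, s_p, ai_qp, c("WASTE", "WASTE"), g, "annihilation")
    }
  }
  builder_crn(bl, rates,
              metadata = list(d_ideal = d_ideal, s_ideal = s_ideal))
}

#' Reporting fragment
#'
#' Links each competitive neuron k to its output class l. The surviving
#' reverse signal `S[k]` reversibly displaces the report strand `RY[k,l]`
#' from the report-summation gate `RE[k,l]` (toehold H, bimolecular both
#' directions); `RY[k,l]` then irreversibly displaces the fluorophore strand
#' `FLUOR[l]` from the quencher-carrying report gate `R[l]` (toehold T),
#' which both sums contributions from all neurons wired to the same output
#' and makes the readout irreversible. `[FLUOR[l]]` is the measured output
#' Y_l.
#'
#' @param prototype_class integer or character vector mapping each
#'   competitive index k to its output class index l (values in `1..l` or
#'   class labels; converted to indices by order of first appearance of the
#'   sorted unique values).
#' @param s_ideal ideal reverse-signal concentrations (nM); sets the recipe
#'   (`RE` at `100% * max s`, `R` at `150% * max s`).
#' @param rates a [rate_table()].
#' @param re,r optional fixed gate concentrations (nM).
#' @return a `crn` fragment.
#' @export
build_reporting <- function(prototype_class, s_ideal, rates = rate_table(),
                            re = NULL, r = NULL) {
  if (anyNA(prototype_class)) stop("unmapped competitive neuron",
                                   call. = FALSE)
  lmap <- as.integer(factor(prototype_class,
                            levels = unique(prototype_class)))
  if (is.numeric(prototype_class)) lmap <- as.integer(prototype_class)
  if (is.null(re)) re <- max(s_ideal)
  if (is.null(r)) r <- 1.5 * max(s_ideal)
  h <- bind_nM(rates, "H")
  tt <- bind_nM(rates, "T")
  bl <- new_builder()
  add_species(bl, "WASTE", "WASTE", 0, "reporting")
  for (l in sort(unique(lmap))) {
    add_species(bl, sp_name("FLUOR", l = l), "FLUOR", 0, "reporting")
    add_species(bl, sp_name("R", l = l), "R", r, "reporting")
  }
  for (k in seq_along(lmap)) {
    l <- lmap[k]
    s_k <- sp_name("S", k = k)
    re_kl <- sp_name("RE", k = k, l = l)
    ry_kl <- sp_name("RY", k = k, l = l)
    rew_kl <- sp_name("REW", k = k, l = l)
    add_species(bl, s_k, "S", 0, "report_summation")
    add_species(bl, re_kl, "RE", re, "report_summation")
    add_species(bl, ry_kl, "RY", 0, "report_summation")
    add_species(bl, rew_kl, "REW", 0, "report_summation")
    add_reaction(bl, s_k, re_kl, c(ry_kl, rew_kl), h, "report_summation")
    add_reaction(bl, ry_kl, rew_kl, c(s_k, re_kl), h, "report_summation")
    add_reaction(bl, ry_kl, sp_name("R", l = l),
                 c(sp_name("FLUOR", l = l), "WASTE"), tt, "reporting")
  }
  builder_crn(bl, rates, metadata = list(class_map = lmap))
}

#' Gate concentration recipe
#'
#' Evaluates the full concentration recipe for one input vector and weight
#' matrix: fuel at `200% * sum_j(a_i + |b_ij|)`; subtraction gates at
#' `120% * max(0, min(a_i, b_ij))` (clamped at zero, so negative-weight
#' channels get no gate); summation gates at `120% * |a_i - b_ij|` and the
#' total gate at `120% * sum_i |a_i - b_ij|`; reversal and reverse-summation
#' gates at `100% * max_j d_j`; annihilation gates at `120% * max_k s_k`;
#' report-summation gates at `100% * max_k s_k` and report gates at
#' `150% * max_k s_k`. Signed weights flow through `|a - b| = a + |b|`, so no
#' special case is needed.
#'
#' @inheritParams build_input_activation
#' @return list with per-gate concentration arrays plus the ideal distances
#'   `d` and ideal reverse signals `s`.
#' @export
recipe_concentrations <- function(a, b) {
  b <- check_ab(a, b)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  absdiff <- abs(a - b)                     # recycles a down columns
  d <- colSums(absdiff)
  n <- ncol(b)
  s <- if (n > 1L) (sum(d) - d) / (n - 1) else d
  list(
    fuel = 2 * (n * a + rowSums(abs(b))),   # 200% * sum_j(a_i + |b_ij|)
    sg = 1.2 * pmax(0, pmin(matrix(a, length(a), n), b)),
    sumx = 1.2 * absdiff,
    sumw = 1.2 * absdiff,
    sum = 1.2 * d,
    srg = max(d),
    rsg = max(d),
    anh = 1.2 * max(s),
    re = max(s),
    r = 1.5 * max(s),
    d = d,
    s = s
  )
}

#' Compile a trained model and one sample into a reaction network
#'
#' One-pot compilation: merges the input-activation, subtraction-annihilation,
#' absolute-value-summation, loser-take-all and reporting fragments with the
#' full gate-concentration recipe, all species present at time zero. The
#' network has `i` input channels, `j` competitive neurons (one per
#' prototype) and `l` fluorescent outputs (one per class).
#'
#' @param model an [lvq()] fit.
#' @param x one sample: numeric vector of length `i` on the raw feature scale
#'   (scaled with the model's stored scaling) or, with `scaled = TRUE`,
#'   already in nM.
#' @param rates a [rate_table()].
#' @param scaled set to `TRUE` when `x` is already on the concentration
#'   scale.
#' @param leak add a parallel leak channel (at the global leak rate) to every
#'   designed bimolecular reaction.
#' @return a `crn` whose metadata records the shape, the ideal distances
#'   `d_ideal`, ideal reverse signals `s_ideal`, the class labels, and the
#'   recipe.
#' @export
compile_network <- function(model, x, rates = rate_table(), scaled = FALSE,
                            leak = FALSE) {
  stopifnot(inherits(model, "lvq"))
  a <- if (scaled) as.numeric(x) else
    as.numeric(scale_features(matrix(as.numeric(x), nrow = 1L),
                              scaling = model$scaling)$samples)
  a <- pmax(a, 0)                       # concentrations cannot be negative
  b <- t(model$weights)                 # i x j
  rec <- recipe_concentrations(a, b)
  lmap <- match(model$prototype_class, model$levels)
  parts <- list(
    build_input_activation(a, b, rates),
    build_subtraction_annihilation(a, b, rates),
    build_abs_summation(a, b, rates),
    build_loser_take_all(rec$d, rates),
    build_reporting(lmap, rec$s, rates)
  )
  net <- merge_crns(parts)
  net$metadata <- c(net$metadata, list(
    shape = c(i = length(a), j = ncol(b), l = length(model$levels)),
    classes = model$levels,
    input = a,
    recipe = rec[c("fuel", "sg", "sumx", "sumw", "sum", "srg", "rsg",
                   "anh", "re", "r")],
    range_max = model$scaling$range_max
  ))
  if (leak) net <- add_leak_channels(net)
  net
}

## Parallel leak channel for every designed bimolecular reaction.
add_leak_channels <- function(net) {
  bi <- !is.na(net$reactions$r2)
  if (!any(bi)) return(net)
  leaks <- net$reactions[bi, , drop = FALSE]
  leaks$rate <- net$rates$leak * 1e-9
  leaks$module <- "leak"
  net$reactions <- rbind(net$reactions, leaks)
  rownames(net$reactions) <- NULL
  net
}

#' Strand census of a compiled network
#'
#' Counts the distinct DNA strand species the network requires as reagents,
#' grouped by emitting module: substrates and fuels of the input-activation
#' module, and the gate strands of the seven downstream modules. The
#' activation factors `IN[i]` carry the sample itself (in the expression
#' setting they are the converted biomarker strands) and are not counted as
#' network reagents; transient intermediates and waste products are likewise
#' excluded. For a 10-input, 3-prototype, 2-output network with all weights
#' positive the total is 180.
#'
#' @param x a compiled `crn`.
#' @return data frame of class `crn_census` with one row per module and a
#'   `total` attribute.
#' @export
census <- function(x) {
  stopifnot(inherits(x, "crn"))
  counted <- c("XSUB", "WSUB", "XFUEL", "SG", "SUMX", "SUMW", "SUM",
               "SRG", "RSG", "ANH", "RE", "R")
  sp <- x$species[x$species$role %in% counted, , drop = FALSE]
  mods <- c("input_activation", "subtraction_annihilation", "abs_summation",
            "signal_reversal", "reverse_summation", "annihilation",
            "report_summation", "reporting")
  n <- vapply(mods, function(m) sum(sp$module == m), 0L)
  out <- data.frame(module = mods, strands = unname(n),
                    stringsAsFactors = FALSE)
  out <- out[out$strands > 0L | mods %in% unique(sp$module), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total = sum(n), class = c("crn_census", "data.frame"))
}

#' @export
print.crn_census <- function(x, ...) {
  cat("DNA strand census (network reagents)\n")
  print.data.frame(x, row.names = FALSE)
  cat("total:", attr(x, "total"), "strands\n")
  invisible(x)
}

#' Standalone Manhattan-distance network for one prototype channel
#'
#' Builds the subtraction-annihilation plus absolute-value-summation network
#' for a single competitive neuron with the input and weight strands already
#' activated (free at time zero), mirroring the module-level validation
#' setups. The ideal final `[D[j=1]]` is `sum(abs(a - b))`.
#'
#' @param a numeric vector of input strand concentrations X (nM).
#' @param b signed weight strand concentrations (nM); negative entries emit
#'   the inert `NW` strand and no subtraction gate.
#' @param rates a [rate_table()].
#' @param sg,sumx,sumw,sum_gate optional fixed gate concentrations (nM);
#'   defaults follow the recipe.
#' @return a `crn` with `metadata$d_ideal`.
#' @export
distance_crn <- function(a, b, rates = rate_table(), sg = NULL,
                         sumx = NULL, sumw = NULL, sum_gate = NULL) {
  stopifnot(length(a) == length(b), all(a >= 0))
  bm <- matrix(b, ncol = 1L)
  parts <- list(
    build_subtraction_annihilation(a, bm, rates, sg = sg),
    build_abs_summation(a, bm, rates, sumx = sumx, sumw = sumw,
                        sum_gate = sum_gate)
  )
  net <- merge_crns(parts)
  ## the strands are pre-activated: set X and W/NW to their free values
  for (i in seq_along(a)) {
    x_nm <- sp_name("X", i = i, j = 1L)
    w_role <- if (b[i] >= 0) "W" else "NW"
    w_nm <- sp_name(w_role, i = i, j = 1L)
    net$species$initial[net$species$name == x_nm] <- a[i]
    net$species$initial[net$species$name == w_nm] <- abs(b[i])
  }
  net$metadata$d_ideal <- sum(abs(a - b))
  net
}

#' Standalone loser-take-all network with reporters
#'
#' Builds the competitive layer plus reporting for given initial distance
#' factors, one output per competitor (identity class map), mirroring the
#' three-input fixtures: reversal and reverse-summation gates at 100 nM,
#' annihilation gates at 108 nM, report-summation gates at 100 nM and report
#' gates at 150 nM by default.
#'
#' @param d initial distance-factor concentrations (nM), length >= 2.
#' @param rates a [rate_table()].
#' @param srg,rsg,anh,re,r gate concentrations (nM).
#' @return a `crn` with `metadata$d_ideal` and `metadata$s_ideal`.
#' @export
lta_crn <- function(d, rates = rate_table(), srg = 100, rsg = 100,
                    anh = 108, re = 100, r = 150) {
  parts <- list(
    build_loser_take_all(d, rates, d_init = d, srg = srg, rsg = rsg,
                         anh = anh),
    build_reporting(seq_along(d), (sum(d) - d) / (length(d) - 1), rates,
                    re = re, r = r)
  )
  merge_crns(parts)
}
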