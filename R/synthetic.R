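with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Synthetic nucleus-morphology-like cohort
#'
#' Generates a two-class cohort of ten Gaussian features emulating the shape
#' of the nucleus-morphology data used for tumor classification: a benign
#' and a malignant class with shifted feature means, values clipped at zero.
#' Defaults mirror the reference cohort sizes (357 benign, 212 malignant
#' cases) with class centers at 400 and 600 nM and a common within-class
#' standard deviation of 100 nM on the working 0-1000 nM concentration scale
#' (a two-standard-deviation mean shift per feature, which gives a strongly
#' but not trivially separable ten-dimensional problem).
#'
#' @param n samples per class, length 2 (benign, malignant).
#' @param n_features number of features i.
#' @param centers length-2 vector (or 2-by-i matrix) of class means.
#' @param sd within-class standard deviation (scalar or per feature).
#' @param labels the two class labels.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return data frame with columns `id`, `label`, `f1..fi`.
#' @export
gen_morphology_like <- function(n = c(357, 212), n_features = 10,
                                centers = c(400, 600), sd = 100,
                                labels = c("benign", "malignant"),
                                seed = 1L) {
  stopifnot(length(n) == 2L, all(n >= 1), sd > 0, n_features >= 1)
  if (is.null(dim(centers))) {
    centers <- rbind(rep(centers[1L], n_features),
                     rep(centers[2L], n_features))
  }
  with_seed(seed, {
    rows <- lapply(1:2, function(cls) {
      m <- matrix(stats::rnorm(n[cls] * n_features,
                               mean = rep(centers[cls, ], each = n[cls]),
                               sd = sd),
                  nrow = n[cls])
      pmax(m, 0)
    })
    x <- do.call(rbind, rows)
    colnames(x) <- paste0("f", seq_len(n_features))
    data.frame(id = seq_len(sum(n)),
               label = factor(rep(labels, times = n), levels = labels),
               x, stringsAsFactors = FALSE)
  })
}

#' Synthetic expression-like cohort
#'
#' Generates a two-class log-normal cohort emulating circulating biomarker
#' expression levels (e.g. serum miRNA abundances): heavy-tailed positive
#' values with a class-specific median shift on a subset of features.
#' Defaults mirror the reference cohort sizes (875 healthy, 1006 carcinoma
#' cases), ten features with baseline median 100, log-sd 0.35 (about a 36%
#' coefficient of variation, typical of serum biomarker panels), and a
#' two-fold median shift on five of the ten features in the carcinoma class.
#' Downstream scaling maps the values onto the 0-1000 nM range.
#'
#' @param n samples per class, length 2 (healthy, case).
#' @param n_features number of features i.
#' @param base_median baseline median expression level.
#' @param sdlog log-scale standard deviation.
#' @param shift fold-change of the median in the case class.
#' @param shifted_features indices of the features carrying the shift.
#' @param labels the two class labels.
#' @param seed integer seed.
#' @return data frame with columns `id`, `label`, `f1..fi`.
#' @export
gen_expression_like <- function(n = c(875, 1006), n_features = 10,
                                base_median = 100, sdlog = 0.35, shift = 2,
                                shifted_features = 1:5,
                                labels = c("healthy", "carcinoma"),
                                seed = 1L) {
  stopifnot(length(n) == 2L, all(n >= 1), sdlog > 0, base_median > 0,
            shift > 0)
  meanlog <- rbind(rep(log(base_median), n_features),
                   rep(log(base_median), n_features))
  meanlog[2L, shifted_features] <- meanlog[2L, shifted_features] + log(shift)
  with_seed(seed, {
    rows <- lapply(1:2, function(cls) {
      matrix(stats::rlnorm(n[cls] * n_features,
                           meanlog = rep(meanlog[cls, ], each = n[cls]),
                           sdlog = sdlog),
             nrow = n[cls])
    })
    x <- do.call(rbind, rows)
    colnames(x) <- paste0("f", seq_len(n_features))
    data.frame(id = seq_len(sum(n)),
               label = factor(rep(labels, times = n), levels = labels),
               x, stringsAsFactors = FALSE)
  })
}

#' Module-level validation fixtures
#'
#' The fixed input/weight/gate combinations used to validate the distance
#' and competitive modules across the three working concentration ranges
#' (0-10, 0-100, 0-1000 nM):
#'
#' * distance fixtures, positive weights: per range r, the combinations
#'   X = W = r, X = 0.2r / W = 0.8r, and X = 0.8r / W = 0.2r, with all four
#'   gates (subtraction, both summation gates and the total-summation gate)
#'   at 1.2 r;
#' * distance fixtures, negative weights: the same three combinations with
#'   the weight strand inert (`NW`), no subtraction gate, and the summation
#'   gates at their recipe values `1.2 * (X + |NW|)` (which equals 1.2 r for
#'   the split combinations); ideal distance X + |NW|;
#' * loser-take-all fixtures: eight ordered triples with `D_1` minimal and at
#'   least two-fold gaps between consecutive inputs, with reversal and
#'   reverse-summation gates at 100 nM, annihilation gates at 108 nM,
#'   report-summation gates at 100 nM and report gates at 150 nM; simulated
#'   to 10000 s.
#'
#' @return a list of class `molvq_fixtures` with elements `distance` (data
#'   frame: name, range, sign, x, w, gate concentrations, ideal, t_end) and
#'   `lta` (list of eight d-triples plus gate settings).
#' @export
module_fixtures <- function() {
  ranges <- c(10, 100, 1000)
  combos <- list(c(1, 1), c(0.2, 0.8), c(0.8, 0.2))
  combo_names <- c("X=W", "X<W", "X>W")
  rows <- list()
  for (r in ranges) {
    for (ci in seq_along(combos)) {
      x <- combos[[ci]][1L] * r
      w <- combos[[ci]][2L] * r
      for (sign in c("positive", "negative")) {
        gates <- if (sign == "positive") {
          list(sg = 1.2 * r, sumx = 1.2 * r, sumw = 1.2 * r, sum = 1.2 * r)
        } else {
          list(sg = NA_real_, sumx = 1.2 * (x + w), sumw = 1.2 * (x + w),
               sum = 1.2 * (x + w))
        }
        ideal <- if (sign == "positive") abs(x - w) else x + w
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("dist_r%g_%s_%s", r, combo_names[ci], sign),
          range = r, sign = sign, x = x, w = w,
          sg = gates$sg, sumx = gates$sumx, sumw = gates$sumw,
          sum = gates$sum, ideal = ideal, t_end = 30000,
          stringsAsFactors = FALSE)
      }
    }
  }
  distance <- do.call(rbind, rows)
  rownames(distance) <- NULL
  lta_d <- list(
    c(10, 20, 40), c(10, 20, 80), c(10, 40, 80), c(20, 40, 80),
    c(10, 30, 60), c(5, 10, 20), c(5, 20, 40), c(25, 50, 100)
  )
  structure(list(
    distance = distance,
    lta = list(d = lta_d,
               gates = list(srg = 100, rsg = 100, anh = 108, re = 100,
                            r = 150),
               t_end = 10000)
  ), class = "molvq_fixtures")
}

#' Run one distance fixture
#'
#' Builds and simulates the single-channel distance network for one row of
#' the fixture table and reports the final distance factor and its
#' full-scale percent error.
#'
#' @param fx one row of `module_fixtures()$distance`.
#' @param rates a [rate_table()].
#' @param ... further arguments to [simulate.crn()].
#' @return list with `final_D`, `ideal`, `error_pct`, `residual_nM`.
#' @export
run_distance_fixture <- function(fx, rates = rate_table(), ...) {
  w_signed <- if (fx$sign == "positive") fx$w else -fx$w
  net <- distance_crn(fx$x, w_signed, rates = rates,
                      sg = if (is.na(fx$sg)) NULL else fx$sg,
                      sumx = fx$sumx, sumw = fx$sumw, sum_gate = fx$sum)
  sim <- simulate(net, t_end = fx$t_end, ...)
  final_d <- unname(sim$final[sp_name("D", j = 1L)])
  list(final_D = final_d, ideal = fx$ideal,
       error_pct = distance_error(final_d, fx$ideal, fx$range),
       residual_nM = abs(final_d - fx$ideal))
}

#' Run one loser-take-all fixture
#'
#' Builds and simulates the three-input competitive network with reporters
#' for one distance triple and reports the normalized reporter endpoints and
#' the index of the winning output.
#'
#' @param d distance-factor triple (nM), `d[1]` expected minimal.
#' @param gates gate concentrations as in `module_fixtures()$lta$gates`.
#' @param t_end horizon in seconds.
#' @param rates a [rate_table()].
#' @param ... further arguments to [simulate.crn()].
#' @return list with `y` (reporter endpoints), `normalized`, `winner`.
#' @export
run_lta_fixture <- function(d, gates = list(srg = 100, rsg = 100, anh = 108,
                                            re = 100, r = 150),
                            t_end = 10000, rates = rate_table(), ...) {
  net <- lta_crn(d, rates = rates, srg = gates$srg, rsg = gates$rsg,
                 anh = gates$anh, re = gates$re, r = gates$r)
  sim <- simulate(net, t_end = t_end, ...)
  y <- sim$final[grep("^FLUOR\\[", sim$species, value = TRUE)]
  l_idx <- as.integer(sub("^FLUOR\\[l=(\\d+)\\]$", "\\1", names(y)))
  y <- unname(y[order(l_idx)])
  list(y = y, normalized = normalize_signal(y), winner = which.max(y))
}

#' Write a cohort as delimited text
#'
#' One row per sample: `id`, `label`, then the feature columns — the same
#' layout [read_cohort()] and the command-line driver consume.
#'
#' @param cohort data frame from [gen_morphology_like()] or
#'   [gen_expression_like()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV file with columns `id`, `label`, features.
#' @return data frame with `label` as factor.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(d)))
  d$label <- factor(d$label)
  d
}
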