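#' Affine feature scaling onto a concentration range
#'
#' Maps every feature column of a raw sample-by-feature table affinely onto
#' `[0, range_max]` nanomolar, so that measured quantities (nucleus morphology
#' means, expression levels) can be represented as DNA strand concentrations.
#' The per-feature minima and maxima are recorded so that the mapping is
#' invertible and can be re-applied to new samples.
#'
#' @param raw_table numeric matrix or data frame, one row per sample, one
#'   column per feature. No missing values are allowed.
#' @param range_max upper end of the target concentration range in nM
#'   (default 1000, the top of the working range of the molecular circuits).
#' @param scaling optional scaling object returned by a previous call; when
#'   supplied, its stored minima/maxima are re-used instead of being
#'   re-estimated (for scaling test samples with the training scale).
#' @return an object of class `lvq_scaled`: a list with `samples` (the scaled
#'   matrix) and `scaling` (list with `min`, `max`, `range_max`).
#' @seealso [unscale_features()]
#' @export
scale_features <- function(raw_table, range_max = 1000, scaling = NULL) {
  x <- as.matrix(raw_table)
  if (!is.numeric(x)) {
    stop("non-numeric cell in feature table", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("feature table contains missing values", call. = FALSE)
  }
  if (!is.numeric(range_max) || length(range_max) != 1L || range_max <= 0) {
    stop("'range_max' must be a single positive concentration (nM)",
         call. = FALSE)
  }
  if (is.null(scaling)) {
    mins <- apply(x, 2L, min)
    maxs <- apply(x, 2L, max)
    if (any(maxs == mins)) {
      bad <- which(maxs == mins)
      stop("constant feature (max = min): column ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    scaling <- list(min = mins, max = maxs, range_max = range_max)
  } else {
    stopifnot(length(scaling$min) == ncol(x))
  }
  scaled <- sweep(x, 2L, scaling$min, "-")
  scaled <- sweep(scaled, 2L, scaling$max - scaling$min, "/") *
    scaling$range_max
  structure(list(samples = scaled, scaling = scaling),
            class = "lvq_scaled")
}

#' Invert the affine feature scaling
#'
#' @param scaled numeric matrix (or vector) of scaled values in nM.
#' @param scaling scaling list as stored by [scale_features()].
#' @return matrix of values on the original feature scale.
#' @export
unscale_features <- function(scaled, scaling) {
  x <- if (is.null(dim(scaled))) matrix(scaled, nrow = 1L) else
    as.matrix(scaled)
  x <- x / scaling$range_max
  x <- sweep(x, 2L, scaling$max - scaling$min, "*")
  sweep(x, 2L, scaling$min, "+")
}

#' Manhattan distance between two concentration vectors
#'
#' The competitive layer of the molecular network scores prototypes by the
#' L1 (Manhattan) distance, which the strand-displacement circuit evaluates as
#' pairwise annihilation followed by summation of the residues. The silicon
#' reference classifier uses the same metric so that both decision paths
#' agree.
#'
#' @param x,w numeric vectors of equal length (nM; `w` may be signed).
#' @return `sum(abs(x - w))`, a non-negative scalar.
#' @export
manhattan_distance <- function(x, w) {
  if (length(x) != length(w)) {
    stop("length mismatch: length(x) = ", length(x),
         ", length(w) = ", length(w), call. = FALSE)
  }
  sum(abs(x - w))
}

## Allocate prototype counts to classes: proportional to class frequency,
## largest-remainder rounding, at least one per class.
allocate_prototypes <- function(n_prototypes, class_counts) {
  k <- length(class_counts)
  raw <- n_prototypes * class_counts / sum(class_counts)
  alloc <- pmax(1L, floor(raw))
  while (sum(alloc) > n_prototypes) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < n_prototypes) {
    rem <- raw - alloc
    i <- which.max(rem)
    alloc[i] <- alloc[i] + 1L
  }
  if (any(alloc < 1L)) stop("cannot give every class a prototype",
                            call. = FALSE)
  alloc
}

#' Train a learning vector quantization classifier
#'
#' Fits an LVQ1 prototype classifier: prototypes are initialised from random
#' training samples of their assigned class, then iteratively pulled toward
#' samples with a matching label and pushed away from samples with a
#' mismatched label. Distances are Manhattan, matching the molecular
#' implementation of the competitive layer. Features are affinely scaled onto
#' `[0, range_max]` nM before training, and the trained prototype matrix is
#' the weight table loaded into the DNA network by [compile_network()].
#'
#' The learning rate decays linearly over epochs,
#' `alpha(e) = lr0 * (1 - (e - 1) / epochs)`, and prototypes of each class are
#' allocated proportionally to class frequency (at least one per class).
#' Training is reproducible from `seed`.
#'
#' @param x feature matrix / data frame (raw scale), or a formula.
#' @param ... passed between methods.
#' @return an object of class `lvq` with components `weights` (j-by-i signed
#'   prototype matrix in nM), `prototype_class` (class label per prototype),
#'   `scaling`, `shape` (named vector `i`, `j`, `l`), `levels`, and `config`.
#' @examples
#' set.seed(1)
#' d <- gen_morphology_like(n = c(40, 40), seed = 1)
#' fit <- lvq(d[, -(1:2)], d$label, n_prototypes = 3, seed = 1)
#' predict(fit, d[1:5, -(1:2)])
#' @export
lvq <- function(x, ...) UseMethod("lvq")

#' @rdname lvq
#' @param formula model formula `label ~ .` style.
#' @param data data frame holding the variables.
#' @export
lvq.formula <- function(formula, data, ...) {
  tt <- stats::terms(formula, data = data)
  mf <- stats::model.frame(tt, data)
  y <- stats::model.response(mf)
  x <- mf[, attr(tt, "term.labels"), drop = FALSE]
  fit <- lvq.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname lvq
#' @param y class labels, one per row of `x` (factor or coercible).
#' @param n_prototypes number of competitive-layer neurons j (>= number of
#'   classes).
#' @param lr0 initial learning rate, in (0, 1).
#' @param epochs number of passes over the training data.
#' @param range_max concentration full scale in nM.
#' @param seed integer seed controlling initialisation and sample order.
#' @export
lvq.default <- function(x, y, n_prototypes = 3L, lr0 = 0.1, epochs = 100L,
                        range_max = 1000, seed = 1L, ...) {
  y <- factor(y)
  lev <- levels(y)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  if (n_prototypes < nlevels(y)) {
    stop("n_prototypes (", n_prototypes, ") < number of classes (",
         nlevels(y), ")", call. = FALSE)
  }
  if (any(table(y) == 0L)) stop("empty class", call. = FALSE)
  sc <- scale_features(x, range_max = range_max)
  xs <- sc$samples
  if (nrow(xs) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)

  alloc <- allocate_prototypes(as.integer(n_prototypes), table(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  proto_class <- rep(lev, times = alloc)
  w <- matrix(0, nrow = sum(alloc), ncol = ncol(xs))
  row <- 1L
  for (ci in seq_along(lev)) {
    idx <- which(y == lev[ci])
    pick <- sample(idx, alloc[ci], replace = length(idx) < alloc[ci])
    for (p in pick) {
      w[row, ] <- xs[p, ]
      row <- row + 1L
    }
  }

  epochs <- as.integer(epochs)
  for (e in seq_len(epochs)) {
    alpha <- lr0 * (1 - (e - 1L) / epochs)
    if (alpha <= 0) next
    for (s in sample.int(nrow(xs))) {
      d <- rowSums(abs(sweep(w, 2L, xs[s, ], "-")))
      jstar <- which.min(d)
      delta <- alpha * (xs[s, ] - w[jstar, ])
      if (proto_class[jstar] == as.character(y[s])) {
        w[jstar, ] <- w[jstar, ] + delta
      } else {
        w[jstar, ] <- w[jstar, ] - delta
      }
    }
  }

  colnames(w) <- colnames(xs)
  structure(list(
    weights = w,
    prototype_class = proto_class,
    scaling = sc$scaling,
    shape = c(i = ncol(w), j = nrow(w), l = nlevels(y)),
    levels = lev,
    config = list(n_prototypes = as.integer(n_prototypes), lr0 = lr0,
                  epochs = epochs, range_max = range_max,
                  seed = as.integer(seed)),
    call = match.call()
  ), class = "lvq")
}

#' Nearest-prototype classification
#'
#' Scores a single already-scaled input vector against every prototype by
#' Manhattan distance. The winning class is that of the closest prototype;
#' ties on the minimum go to the lowest prototype index and are flagged.
#'
#' @param model an `lvq` fit.
#' @param x numeric vector on the model's scaled concentration range (nM).
#' @return list with `class`, `distances` (d_j per prototype), `margin`
#'   (second-smallest minus smallest distance) and `tie` flag.
#' @export
classify_nearest <- function(model, x) {
  stopifnot(inherits(model, "lvq"))
  if (length(x) != ncol(model$weights)) {
    stop("dimension mismatch: input has ", length(x), " features, model has ",
         ncol(model$weights), call. = FALSE)
  }
  d <- rowSums(abs(sweep(model$weights, 2L, x, "-")))
  ord <- order(d)
  jstar <- which.min(d)               # ties: lowest index
  margin <- if (length(d) > 1L) d[ord[2L]] - d[ord[1L]] else Inf
  list(class = model$prototype_class[jstar],
       distances = d,
       margin = margin,
       tie = isTRUE(margin == 0))
}

#' @rdname lvq
#' @param object,newdata an `lvq` fit and raw-scale feature rows.
#' @param type `"class"` for labels, `"distance"` for the full prototype
#'   distance matrix (plus winner columns).
#' @export
predict.lvq <- function(object, newdata,
                        type = c("class", "distance"), ...) {
  type <- match.arg(type)
  xs <- scale_features(newdata, scaling = object$scaling)$samples
  res <- lapply(seq_len(nrow(xs)), function(r)
    classify_nearest(object, xs[r, ]))
  cls <- factor(vapply(res, `[[`, "", "class"), levels = object$levels)
  if (type == "class") return(cls)
  d <- t(vapply(res, `[[`, numeric(nrow(object$weights)), "distances"))
  colnames(d) <- paste0("d_", seq_len(ncol(d)))
  data.frame(d, class = cls,
             margin = vapply(res, `[[`, 0, "margin"),
             tie = vapply(res, `[[`, NA, "tie"))
}

#' @export
print.lvq <- function(x, ...) {
  cat("Learning vector quantization classifier (LVQ1, Manhattan metric)\n")
  cat(sprintf("  shape: i = %d features, j = %d prototypes, l = %d classes\n",
              x$shape["i"], x$shape["j"], x$shape["l"]))
  cat("  prototype classes:", paste(x$prototype_class, collapse = ", "), "\n")
  cat(sprintf("  concentration range: [0, %g] nM\n", x$scaling$range_max))
  invisible(x)
}

#' @export
coef.lvq <- function(object, ...) object$weights

#' @export
summary.lvq <- function(object, ...) {
  structure(list(fit = object,
                 weight_range = range(object$weights),
                 negative_weights = sum(object$weights < 0)),
            class = "summary.lvq")
}

#' @export
print.summary.lvq <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weight range: [%.3g, %.3g] nM; %d negative weight(s)\n",
              x$weight_range[1], x$weight_range[2], x$negative_weights))
  invisible(x)
}

#' Choose the number of prototypes by stratified K-fold cross-validation
#'
#' Evaluates each candidate prototype count by stratified K-fold
#' cross-validation of the LVQ1 fit and returns the candidate with the highest
#' mean validation accuracy; ties are broken toward the smaller count.
#'
#' @param x,y features (raw scale) and labels.
#' @param candidates integer vector of prototype counts to compare.
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment and training.
#' @param ... further arguments to [lvq()].
#' @return list with `best` (chosen count) and `table`
#'   (data frame candidate / mean_accuracy).
#' @export
kfold_select_prototypes <- function(x, y, candidates, k = 5L, seed = 1L,
                                    ...) {
  y <- factor(y)
  x <- as.matrix(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (lev in levels(y)) {              # stratified fold assignment
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k)) {
    if (nlevels(droplevels(y[fold != f])) < nlevels(y)) {
      stop("fold ", f, " training split is missing a class", call. = FALSE)
    }
  }
  acc <- vapply(candidates, function(np) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- lvq(x[tr, , drop = FALSE], y[tr], n_prototypes = np,
                 seed = as.integer(seed) + f, ...)
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(fold_acc)
  }, 0)
  tab <- data.frame(candidate = candidates, mean_accuracy = acc)
  best <- candidates[order(-acc, candidates)][1L]
  list(best = best, table = tab)
}

#' Persist a trained model as JSON
#'
#' @param model an `lvq` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lvq <- function(model, path) {
  stopifnot(inherits(model, "lvq"))
  obj <- list(
    weights = model$weights,
    prototype_class = model$prototype_class,
    scaling = model$scaling,
    shape = as.list(model$shape),
    levels = model$levels,
    config = model$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_lvq()]
#'
#' @param path JSON file.
#' @return an `lvq` object.
#' @export
read_lvq <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  if (!is.matrix(w)) w <- matrix(w, nrow = length(obj$prototype_class),
                                 byrow = TRUE)
  structure(list(
    weights = w,
    prototype_class = obj$prototype_class,
    scaling = list(min = obj$scaling$min, max = obj$scaling$max,
                   range_max = obj$scaling$range_max),
    shape = c(i = obj$shape$i, j = obj$shape$j, l = obj$shape$l),
    levels = obj$levels,
    config = obj$config,
    call = quote(read_lvq())
  ), class = "lvq")
}
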