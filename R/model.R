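# All OLS quantities needed by the selection loop (RSS, coefficients,
# partial-F tests) are computed from the Gram matrix X'X, X'y and y'y, so
# each add/drop step costs O(p k^2) independent of the row count.

#' Bidirectional stepwise linear regression
#'
#' Forward-backward predictor selection for an ordinary least-squares
#' model. Each round first drops any included feature whose partial-F
#' p-value exceeds the exit threshold (worst first), then admits the best
#' excluded candidate whose entry p-value passes the entry threshold; it
#' stops when no move is possible, the fit is numerically exact, or
#' `max_steps` moves were taken. Entry p-values are Bonferroni-adjusted
#' across the current candidate pool, so a large pool of pure-noise
#' features is admitted at rate ~`entry` overall rather than per feature;
#' exit tests use raw p-values. An AIC criterion is available as an
#' alternative. Exact score ties are resolved toward the lowest column
#' index.
#'
#' @param X Numeric feature matrix (columns named).
#' @param y Numeric response aligned with the rows of `X`.
#' @param entry,exit Entry and exit thresholds on the p-value criterion
#'   (`exit >= entry` prevents add/drop cycling).
#' @param criterion `"pF"` (partial-F p-values, default) or `"AIC"`.
#' @param max_steps Cap on total add/drop moves.
#' @return Object of class `pb_linear_model`: `intercept`, named
#'   `coefficients` over the selected subset, `sigma2` (residual variance),
#'   and bookkeeping fields.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("x", 1:6)))
#' fit <- stepwise_fit(X, 2 + 3 * X[, 1] + rnorm(100, sd = 0.1))
#' fit$coefficients
#' @export
stepwise_fit <- function(X, y, entry = 0.01, exit = 0.05,
                         criterion = c("pF", "AIC"), max_steps = 100) {
  criterion <- match.arg(criterion)
  if (exit < entry) stop("exit threshold must be >= entry threshold")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) stop("X rows and y must align")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- mean(y)
  yc <- y - ybar
  usable <- which(colSums(Xc^2) / n > 1e-12)
  G <- crossprod(Xc[, usable, drop = FALSE])
  g <- as.numeric(crossprod(Xc[, usable, drop = FALSE], yc))
  yy <- sum(yc^2)
  p <- length(usable)

  S <- integer(0)        # indices into `usable`
  rss <- yy
  A <- matrix(0, 0, 0)   # inverse Gram of the selected subset
  beta <- numeric(0)
  steps <- 0
  tol <- max(yy, 1) * 1e-12

  refit <- function(S) {
    A <<- solve(G[S, S, drop = FALSE])
    beta <<- as.numeric(A %*% g[S])
    rss <<- yy - sum(beta * g[S])
  }

  repeat {
    moved <- FALSE
    # backward phase: evict until every included feature passes the exit test
    while (length(S) > 0 && steps < max_steps) {
      df <- n - length(S) - 1
      fdrop <- beta^2 / (diag(A) * rss / df)
      pdrop <- stats::pf(fdrop, 1, df, lower.tail = FALSE)
      if (criterion == "AIC") {
        dAIC <- n * log((rss + beta^2 / diag(A)) / rss) - 2  # AIC change on drop
        worst <- which.min(dAIC)
        if (dAIC[worst] >= 0) break
      } else {
        worst <- which.max(pdrop)
        if (rss < tol || pdrop[worst] <= exit) break
      }
      S <- S[-worst]
      if (length(S)) refit(S) else { rss <- yy; A <- matrix(0, 0, 0); beta <- numeric(0) }
      steps <- steps + 1
      moved <- TRUE
    }
    # forward phase: admit the best candidate that passes the entry test
    cand <- setdiff(seq_len(p), S)
    if (length(cand) == 0 || steps >= max_steps || rss < tol) break
    if (length(S) > 0) {
      GcS <- G[cand, S, drop = FALSE]
      u <- as.numeric(GcS %*% beta)
      schur <- diag(G)[cand] - rowSums((GcS %*% A) * GcS)
      num <- (g[cand] - u)^2
    } else {
      schur <- diag(G)[cand]
      num <- g[cand]^2
    }
    ok <- schur > diag(G)[cand] * 1e-10
    drop_rss <- ifelse(ok, num / pmax(schur, .Machine$double.xmin), -Inf)
    rss_new <- rss - drop_rss
    df2 <- n - length(S) - 2
    Fadd <- drop_rss / pmax(rss_new, .Machine$double.xmin) * df2
    padd <- stats::pf(Fadd, 1, df2, lower.tail = FALSE)
    padd[!ok] <- 1
    if (criterion == "AIC") {
      dAIC <- n * log(pmax(rss_new, tol) / rss) + 2
      best <- which.min(dAIC)
      admit <- dAIC[best] < 0
    } else {
      padj <- pmin(1, padd * sum(ok))
      best <- which.min(padj)
      admit <- padj[best] < entry
    }
    if (!admit && !moved) break
    if (admit) {
      S <- c(S, cand[best])
      refit(S)
      steps <- steps + 1
    } else if (!moved) break
  }

  sel <- usable[S]
  b <- beta
  names(b) <- colnames(X)[sel]
  structure(list(intercept = ybar - sum(b * xbar[sel]),
                 coefficients = b,
                 sigma2 = rss / max(n - length(S) - 1, 1),
                 rss = rss, n = n, steps = steps,
                 criterion = criterion, entry = entry, exit = exit),
            class = "pb_linear_model")
}

#' @export
predict.pb_linear_model <- function(object, newdata, ...) {
  if (length(object$coefficients) == 0)
    return(rep(object$intercept, nrow(newdata)))
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  as.numeric(object$intercept +
    as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
      object$coefficients)
}

#' @export
print.pb_linear_model <- function(x, ...) {
  cat("Stepwise linear model:", length(x$coefficients),
      "features, residual sd", sprintf("%.4g", sqrt(x$sigma2)), "\n")
  invisible(x)
}

#' Train the sequence-to-structure Q16 predictor
#'
#' Fits 16 bidirectional stepwise linear regressions, one per Protein
#' Block, each predicting the similarity `1/(lambda + RMSD)` of a fragment
#' to that block from sequence-derived features (reduced-alphabet RMSD
#' statistics and physicochemical transforms). Features are z-scored on the
#' training set; the scaling, the identity-class statistics and the full
#' feature configuration are bundled with the models so prediction is a
#' deterministic function of sequence alone. No homology information is
#' used anywhere.
#'
#' @param fragments Training fragments: a list or data.frame with `seq`
#'   (5-mers), `context` (sequence windows of width `5 + 2 * flank`, padded
#'   with `X` at chain edges) and `D` (n x 16 matrix of structural
#'   coordinates in alphabet order), as produced by [corpus_fragments()].
#' @param config A [feature_config()].
#' @param entry,exit,criterion,max_steps Passed to [stepwise_fit()].
#' @return Object of class `pb_predictor` with `models` (16 stepwise fits in
#'   alphabet order), `feature_stats`, `scaling`, `lambda`, and `labels`.
#' @export
train_predictor <- function(fragments, config = feature_config(),
                            entry = 0.01, exit = 0.05,
                            criterion = "pF", max_steps = 100) {
  D <- as.matrix(fragments$D)
  if (ncol(D) != 16) stop("fragments$D must hold 16 distance columns")
  if (any(apply(D, 2, stats::var) < 1e-12))
    stop("degenerate corpus: a Protein Block has zero variance in targets")
  fs <- fit_feature_stats(fragments$seq, D, config)
  X <- generate_features(fragments$seq, fragments$context, fs)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xz <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- pb_similarity(D, config$lambda)
  models <- lapply(seq_len(16), function(i)
    stepwise_fit(Xz, Y[, i], entry = entry, exit = exit,
                 criterion = criterion, max_steps = max_steps))
  labels <- colnames(D)
  if (is.null(labels)) labels <- letters[1:16]
  names(models) <- labels
  structure(list(models = models, feature_stats = fs,
                 scaling = list(center = ctr, scale = scl),
                 lambda = config$lambda, labels = labels),
            class = "pb_predictor")
}

#' @export
print.pb_predictor <- function(x, ...) {
  cat("Q16 predictor: 16 stepwise models,",
      sum(vapply(x$models, function(m) length(m$coefficients), integer(1))),
      "selected coefficients in total, lambda =", x$lambda, "\n")
  invisible(x)
}

#' Predicted per-block similarities for sequence windows
#'
#' @param predictor A [train_predictor()] result.
#' @param seqs Character vector of query 5-mers.
#' @param contexts Matching sequence contexts (see [train_predictor()]).
#' @return Numeric n x 16 matrix of predicted similarities (1/Angstrom).
#' @export
predict_similarities <- function(predictor, seqs, contexts = NULL) {
  X <- generate_features(seqs, contexts, predictor$feature_stats)
  Xz <- sweep(sweep(X, 2, predictor$scaling$center), 2,
              predictor$scaling$scale, "/")
  out <- vapply(predictor$models, function(m) predict(m, Xz),
                numeric(nrow(Xz)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- predictor$labels
  out
}

#' Classify 5-mers into the 16 Protein Block classes from sequence
#'
#' Predicts the 16 block similarities for each window and returns the label
#' with the highest predicted similarity (upper case, matching the RMSD
#' assignment it emulates). Ties break to the alphabetically first label.
#' The decision is invariant under any strictly increasing transform
#' applied to all 16 scores.
#'
#' @inheritParams predict_similarities
#' @return List with `labels` (character) and `similarities` (n x 16).
#' @export
classify_q16 <- function(predictor, seqs, contexts = NULL) {
  sim <- predict_similarities(predictor, seqs, contexts)
  list(labels = toupper(predictor$labels[max.col(sim, ties.method = "first")]),
       similarities = sim)
}

#' Evaluate a Q16 classification
#'
#' @param predicted,truth Equal-length label vectors (case-insensitive);
#'   truth is normally the RMSD-nearest-block assignment.
#' @return Object of class `pb_evaluation`: overall `accuracy`, `per_label`
#'   accuracy stratified by the true label, and the 16 x 16 `confusion`
#'   matrix (rows = truth).
#' @export
evaluate_q16 <- function(predicted, truth) {
  predicted <- tolower(predicted)
  truth <- tolower(truth)
  if (length(predicted) != length(truth)) stop("label vectors must align")
  labs <- letters[1:16]
  if (!all(c(predicted, truth) %in% labs))
    stop("labels outside the 16-block alphabet")
  confusion <- table(factor(truth, labs), factor(predicted, labs))
  per <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(accuracy = sum(diag(confusion)) / length(truth),
                 per_label = per, confusion = confusion),
            class = "pb_evaluation")
}

#' @export
print.pb_evaluation <- function(x, ...) {
  cat(sprintf("Q16 accuracy: %.1f%% over %d fragments\n",
              100 * x$accuracy, sum(x$confusion)))
  invisible(x)
}

#' Serialize / restore a trained predictor (JSON)
#'
#' Stores coefficients, feature scaling, identity-class statistics,
#' reduced-alphabet maps, the property table, lambda and all configuration
#' needed to regenerate features deterministically.
#'
#' @param predictor A `pb_predictor`.
#' @param path Output (input) JSON file.
#' @return `read_predictor` returns the restored `pb_predictor`;
#'   `write_predictor` returns `path` invisibly.
#' @export
write_predictor <- function(predictor, path) {
  fs <- predictor$feature_stats
  cfg <- fs$config
  obj <- list(
    format = "pbcoords-predictor-1",
    lambda = predictor$lambda,
    labels = predictor$labels,
    models = lapply(predictor$models, function(m)
      list(intercept = m$intercept,
           features = names(m$coefficients),
           coefficients = unname(m$coefficients),
           sigma2 = m$sigma2)),
    scaling = list(names = names(predictor$scaling$center),
                   center = unname(predictor$scaling$center),
                   scale = unname(predictor$scaling$scale)),
    config = list(flank = cfg$flank, lambda = cfg$lambda,
                  periods = cfg$periods,
                  properties = list(names = colnames(cfg$property_table),
                                    residues = rownames(cfg$property_table),
                                    values = unname(cfg$property_table)),
                  alphabets = lapply(cfg$alphabets, function(ra)
                    list(name = ra$name, maps = lapply(ra$maps, as.list)))),
    class_stats = lapply(fs$stats, function(st)
      list(keys = rownames(st$mu), n_occ = unname(st$n_occ),
           mu = unname(st$mu), sigma = unname(st$sigma),
           global = list(mu0 = unname(st$global$mu0),
                         sigma0 = unname(st$global$sigma0),
                         n = st$global$n))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "pbcoords-predictor-1"))
    stop("not a pbcoords predictor file")
  prop <- obj$config$properties$values
  dimnames(prop) <- list(obj$config$properties$residues,
                         obj$config$properties$names)
  alphabets <- lapply(obj$config$alphabets, function(a)
    reduced_alphabet(lapply(a$maps, unlist), a$name))
  names(alphabets) <- vapply(alphabets, function(a) a$name, character(1))
  cfg <- feature_config(alphabets = alphabets, property_table = prop,
                        flank = obj$config$flank, lambda = obj$config$lambda,
                        periods = obj$config$periods)
  stats_list <- lapply(obj$class_stats, function(st) {
    mu <- st$mu; sigma <- st$sigma
    dimnames(mu) <- dimnames(sigma) <- list(st$keys, obj$labels)
    structure(list(n_occ = stats::setNames(as.integer(st$n_occ), st$keys),
                   mu = mu, sigma = sigma,
                   global = list(mu0 = st$global$mu0,
                                 sigma0 = st$global$sigma0,
                                 n = st$global$n)),
              class = "pb_class_stats")
  })
  fs <- structure(list(stats = stats_list, config = cfg),
                  class = "pb_feature_stats")
  models <- lapply(obj$models, function(m)
    structure(list(intercept = m$intercept,
                   coefficients = stats::setNames(m$coefficients, m$features),
                   sigma2 = m$sigma2),
              class = "pb_linear_model"))
  structure(list(models = models, feature_stats = fs,
                 scaling = list(center = stats::setNames(obj$scaling$center,
                                                         obj$scaling$names),
                                scale = stats::setNames(obj$scaling$scale,
                                                        obj$scaling$names)),
                 lambda = obj$lambda, labels = obj$labels),
            class = "pb_predictor")
}
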