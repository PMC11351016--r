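# ddG regression stage: feature-table assembly with exclusion bookkeeping,
# gradient-boosted trees, and 10-fold cross-validation reporting the
# Pearson correlation and RMSE.

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation; errors on degenerate input rather
#' than returning `NA`.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`, both with nonzero
#'   variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  cor(x, y)
}

#' Root-mean-square error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`, in the units of the inputs
#'   (kcal/mol for ddG).
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  sqrt(mean((pred - obs)^2))
}

#' @noRd
.one_hot_aa <- function(aa, prefix) {
  m <- matrix(0, length(aa), 20,
              dimnames = list(NULL, paste0(prefix, "_", names(.AA3))))
  m[cbind(seq_along(aa), match(aa, names(.AA3)))] <- 1
  m
}

#' @noRd
.one_hot_region <- function(region) {
  lv <- c("interior", "surface", "support", "rim", "core")
  m <- matrix(0, length(region), 5, dimnames = list(NULL, paste0("region_", lv)))
  ok <- !is.na(region)
  m[cbind(which(ok), match(region[ok], lv))] <- 1
  m
}

#' Assemble the ddG feature table
#'
#' One row per mutation record: persistent-Laplacian spectral feature
#' blocks, one-hot encodings of the wild-type and mutant amino acids, a
#' one-hot of the mutated residue's structural region (five rASA classes),
#' and an optional external embedding block from a sidecar table. Records
#' whose structure (or residue) cannot be resolved are not silently
#' dropped: they are collected into an exclusion report, mirroring how
#' restricted complexes are excluded from benchmark sets. With
#' `reverse = TRUE` every record is augmented with its reverse mutation
#' (swapped wild-type/mutant one-hots, negated ddG, identical spectral
#' block); a reverse record shares its `pair_id` with its direct record so
#' fold assignment can keep them together.
#'
#' @param records data frame with columns `complex`, `mutation`, `ddg`
#'   (see [read_mutation_table()] / [make_ddg_table()]).
#' @param structures named list of `complex_structure` objects (names =
#'   complex IDs), or a directory containing `<id>.pdb` files.
#' @param config a [pl_feature_config()].
#' @param reverse augment with reverse mutations (default `TRUE`).
#' @param include_regions attach the region one-hot block (default `TRUE`;
#'   requires computing rASA per complex).
#' @param embeddings optional data frame with columns `complex`, `mutation`
#'   and numeric embedding columns, joined by record.
#' @param features optional precomputed spectral feature matrix (row per
#'   record, e.g. from [make_ddg_table()]) to skip recomputation.
#' @param partners partner split used when reading structures from disk.
#' @return a `ddg_feature_table`: list with `features` (numeric matrix),
#'   `meta` (data frame `complex`, `mutation`, `ddg`, `direction`,
#'   `pair_id`), `exclusions` (data frame `complex`, `mutation`, `reason`)
#'   and `layout`.
#' @export
build_feature_table <- function(records, structures,
                                config = pl_feature_config_compact(),
                                reverse = TRUE, include_regions = TRUE,
                                embeddings = NULL, features = NULL,
                                partners = "A:B") {
  stopifnot(is.data.frame(records), all(c("complex", "mutation", "ddg") %in%
                                          names(records)))
  get_structure <- function(id) {
    if (is.list(structures)) return(structures[[id]])
    f <- file.path(structures, paste0(id, ".pdb"))
    if (file.exists(f)) read_structure(f, partners, id = id) else NULL
  }
  region_cache <- list()
  rows <- list(); meta <- list(); excl <- list(); layout <- NULL
  for (i in seq_len(nrow(records))) {
    id <- records$complex[i]
    st <- get_structure(id)
    if (is.null(st)) {
      excl[[length(excl) + 1]] <- data.frame(
        complex = id, mutation = records$mutation[i],
        reason = "structure unavailable", stringsAsFactors = FALSE)
      next
    }
    mu <- tryCatch(parse_mutation(records$mutation[i], id, records$ddg[i]),
                   error = function(e) e)
    if (inherits(mu, "error")) {
      excl[[length(excl) + 1]] <- data.frame(
        complex = id, mutation = records$mutation[i],
        reason = conditionMessage(mu), stringsAsFactors = FALSE)
      next
    }
    spec <- if (!is.null(features)) features[i, ] else
      tryCatch(spectral_features(st, mu, config), error = function(e) e)
    if (inherits(spec, "error")) {
      excl[[length(excl) + 1]] <- data.frame(
        complex = id, mutation = records$mutation[i],
        reason = conditionMessage(spec), stringsAsFactors = FALSE)
      next
    }
    if (is.null(layout) && !is.null(attr(spec, "layout")))
      layout <- attr(spec, "layout")

    region <- NA_character_
    if (include_regions) {
      if (is.null(region_cache[[id]]))
        region_cache[[id]] <- classify_regions(st)
      reg <- region_cache[[id]]
      m <- match(.residue_key(mu$chain, mu$resno, mu$icode),
                 .residue_key(reg$chain, reg$resno, reg$icode))
      region <- reg$region[m]
    }
    emb <- numeric(0)
    if (!is.null(embeddings)) {
      em <- embeddings[embeddings$complex == id &
                         embeddings$mutation == records$mutation[i], , drop = FALSE]
      ecols <- setdiff(names(embeddings), c("complex", "mutation"))
      emb <- if (nrow(em) == 1) as.numeric(em[1, ecols]) else
        rep(0, length(ecols))
      names(emb) <- paste0("emb_", ecols)
    }
    base <- c(as.numeric(spec), emb)
    names(base) <- c(names(spec), names(emb))
    directions <- if (reverse) c("direct", "reverse") else "direct"
    for (dir_ in directions) {
      wt <- if (dir_ == "direct") mu$wt else mu$mut
      mt <- if (dir_ == "direct") mu$mut else mu$wt
      row <- c(base,
               .one_hot_aa(wt, "wt")[1, ], .one_hot_aa(mt, "mut")[1, ],
               if (include_regions) .one_hot_region(region)[1, ])
      rows[[length(rows) + 1]] <- row
      meta[[length(meta) + 1]] <- data.frame(
        complex = id, mutation = records$mutation[i],
        ddg = if (dir_ == "direct") records$ddg[i] else -records$ddg[i],
        direction = dir_, pair_id = i, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no records could be featurized")
  structure(list(features = do.call(rbind, rows),
                 meta = do.call(rbind, meta),
                 exclusions = if (length(excl)) do.call(rbind, excl) else
                   data.frame(complex = character(0), mutation = character(0),
                              reason = character(0)),
                 layout = layout),
            class = "ddg_feature_table")
}

#' @export
print.ddg_feature_table <- function(x, ...) {
  cat("ddg_feature_table:", nrow(x$features), "rows x", ncol(x$features),
      "features;", nrow(x$exclusions), "excluded record(s)\n")
  invisible(x)
}

# correlation for model evaluation: a constant prediction vector (possible
# when boosting stops immediately on pure-noise labels) carries no linear
# association, scored 0 rather than erroring
#' @noRd
.safe_rp <- function(pred, obs) {
  if (var(pred) == 0 || var(obs) == 0) return(0)
  cor(pred, obs)
}

#' Cross-validated ddG regression
#'
#' K-fold cross-validation of a gradient-boosted tree regression of ddG on
#' the feature table. Folds are drawn at the mutation-pair level by default
#' (a mutation and its reverse always share a fold, preventing trivial
#' leakage) with an optional complex-grouped mode in which all mutations of
#' a complex share a fold. Each fold's model trains with early stopping on
#' a 5% validation slice of its training split; out-of-fold predictions
#' are pooled and scored with [pearson_r()] and [rmse()], per fold and
#' pooled.
#'
#' @param table a `ddg_feature_table` (or list with `features` and `meta`).
#' @param folds number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and the learner.
#' @param group_by_complex assign whole complexes to folds (default
#'   `FALSE`: pair-level folds, the common protocol for symmetric
#'   direct/reverse benchmark sets).
#' @param nrounds boosting-round ceiling (default 10000; early stopping
#'   normally ends far sooner).
#' @param early_stopping_rounds patience for early stopping.
#' @param params xgboost parameter overrides; defaults are
#'   `max_depth = 7`, `eta = 0.01`, `subsample = 0.8`,
#'   `colsample_bytree = 0.8`, single-thread for reproducibility.
#' @return a `ddg_cv` object: per-fold and pooled `r_p` and `rmse`
#'   (kcal/mol), the fold assignment, pooled out-of-fold predictions, and
#'   the configuration used. A fold whose model predicts a constant
#'   (possible on pure-noise labels) scores `r_p = 0`, the no-association
#'   value.
#' @export
crossvalidate <- function(table, folds = 10, seed = 1,
                          group_by_complex = FALSE, nrounds = 10000,
                          early_stopping_rounds = 50, params = list()) {
  X <- table$features; meta <- table$meta
  if (nrow(X) < folds) stop("fewer rows than folds")
  group <- if (group_by_complex) meta$complex else
    if (!is.null(meta$pair_id)) meta$pair_id else seq_len(nrow(X))
  ug <- unique(group)
  if (length(ug) < folds)
    stop("only ", length(ug), " groups for ", folds,
         " folds; reduce the number of folds")
  p <- c(list(max_depth = 7, eta = 0.01, subsample = 0.8,
              colsample_bytree = 0.8, objective = "reg:squarederror",
              nthread = 1), params)
  p <- p[!duplicated(names(p), fromLast = TRUE)]

  fold_of_group <- .with_seed(seed, setNames(sample(rep(seq_len(folds),
                                                        length.out = length(ug))),
                                             ug))
  fold <- unname(fold_of_group[as.character(group)])

  pred <- rep(NA_real_, nrow(X))
  per_fold <- data.frame(fold = seq_len(folds), r_p = NA_real_, rmse = NA_real_)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    val <- .with_seed(seed + f, sample(tr, max(2, round(0.05 * length(tr)))))
    tr2 <- setdiff(tr, val)
    dtrain <- xgboost::xgb.DMatrix(X[tr2, , drop = FALSE], label = meta$ddg[tr2])
    dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = meta$ddg[val])
    fit <- .with_seed(seed + f, xgboost::xgb.train(
      params = c(p, list(seed = seed + f)), data = dtrain, nrounds = nrounds,
      evals = list(val = dval),
      early_stopping_rounds = early_stopping_rounds, verbose = 0))
    pred[te] <- predict(fit, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
    per_fold$r_p[f] <- .safe_rp(pred[te], meta$ddg[te])
    per_fold$rmse[f] <- rmse(pred[te], meta$ddg[te])
  }
  structure(list(
    r_p = .safe_rp(pred, meta$ddg),
    rmse = rmse(pred, meta$ddg),
    per_fold = per_fold,
    r_p_mean = mean(per_fold$r_p), r_p_sd = sd(per_fold$r_p),
    rmse_mean = mean(per_fold$rmse), rmse_sd = sd(per_fold$rmse),
    fold = fold, predictions = pred, observed = meta$ddg,
    seed = seed, folds = folds, group_by_complex = group_by_complex,
    params = p, nrounds = nrounds),
    class = "ddg_cv")
}

#' @export
print.ddg_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated ddG regression (seed %d%s)\n",
              x$folds, x$seed,
              if (x$group_by_complex) ", complex-grouped folds" else ""))
  cat(sprintf("  pooled  R_p = %.3f, RMSE = %.3f kcal/mol\n", x$r_p, x$rmse))
  cat(sprintf("  per-fold R_p = %.3f +/- %.3f, RMSE = %.3f +/- %.3f kcal/mol\n",
              x$r_p_mean, x$r_p_sd, x$rmse_mean, x$rmse_sd))
  invisible(x)
}

#' @export
summary.ddg_cv <- function(object, ...) {
  print(object)
  cat("\nper-fold metrics:\n")
  print(object$per_fold, row.names = FALSE, digits = 3)
  invisible(object)
}
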