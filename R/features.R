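#' Preset enrichment radii (bp) for epigenetic markers
#'
#' Published radii: 50 kb for RNA-seq and the histone marks H3K4me1, H3K4me3,
#' H3K9me3, H3K27ac, H3K36me3; 50 bp for DNase I and ATAC-seq; 10 bp for
#' MNase-seq.
#'
#' @param name marker name (case-insensitive).
#' @return radius in bp.
#' @export
marker_radius_preset <- function(name) {
  presets <- c(rna = 50000, h3k4me1 = 50000, h3k4me3 = 50000,
               h3k9me3 = 50000, h3k27ac = 50000, h3k36me3 = 50000,
               dnase = 50, atac = 50, mnase = 10)
  key <- tolower(gsub("[-_ ]", "", name))
  key <- sub("seq$", "", key)
  if (!key %in% names(presets)) stop("no preset radius for marker: ", name)
  unname(presets[key])
}

#' Describe an epigenetic marker track
#'
#' @param name marker name; used to look up the preset radius when `radius`
#'   is not given.
#' @param frags [fragments()] table of the marker's reads.
#' @param radius window radius in bp (overrides the preset).
#' @param library_size RPM denominator.
#' @return list of class `marker_spec`.
#' @export
marker_spec <- function(name, frags, radius = NULL, library_size = NULL) {
  radius <- radius %||% marker_radius_preset(name)
  structure(list(name = name, frags = frags, radius = radius,
                 library_size = frag_library_size(frags, library_size)),
            class = "marker_spec")
}

#' Per-site marker enrichment (RPM in a +/- radius window)
#'
#' @param sites site table.
#' @param marker a [marker_spec()].
#' @return numeric vector, one RPM per site.
#' @export
marker_window_rpm <- function(sites, marker) {
  vapply(seq_len(nrow(sites)), function(i) {
    window_rpm(marker$frags, sites[i, ], width = 2 * marker$radius,
               library_size = marker$library_size)
  }, numeric(1))
}

#' Build the per-site feature matrix
#'
#' The mismatch block is a binary indicator per protospacer position (20
#' columns, `mm_pos01` = adjacent to the PAM .. `mm_pos20` = PAM-distal end;
#' 1 when the site mismatches the guide at that position). The epigenetic
#' block holds one RPM column per marker. Either block can be switched off. An
#' optional base-identity expansion (`expand_bases = TRUE`) replaces each
#' binary indicator with four per-base indicators of the substituted genomic
#' base (80 columns).
#'
#' @param sites site table (with `mismatches` populated; see
#'   [target_sites()]).
#' @param markers list of [marker_spec()] objects.
#' @param use_mismatch,use_epigenetic include the respective feature family.
#' @param expand_bases use the 20 x 4 substituted-base encoding instead of the
#'   binary per-position encoding.
#' @param g genome, required only when `expand_bases = TRUE`.
#' @return data.frame of features, rows aligned with `sites`.
#' @export
build_feature_matrix <- function(sites, markers = list(),
                                 use_mismatch = TRUE, use_epigenetic = TRUE,
                                 expand_bases = FALSE, g = NULL) {
  if (nrow(sites) == 0L) stop("no sites")
  if (!use_mismatch && !use_epigenetic) {
    stop("at least one feature family must be enabled")
  }
  blocks <- list()
  if (use_mismatch) {
    if (!expand_bases) {
      mmat <- matrix(0L, nrow(sites), 20L,
                     dimnames = list(NULL, sprintf("mm_pos%02d", 1:20)))
      for (i in seq_len(nrow(sites))) {
        pos <- sites$mismatches[[i]]
        if (length(pos)) mmat[i, pos] <- 1L
      }
    } else {
      if (is.null(g)) stop("expand_bases = TRUE requires the genome")
      bases <- c("A", "C", "G", "T")
      mmat <- matrix(0L, nrow(sites), 80L,
                     dimnames = list(NULL, as.vector(outer(
                       bases, sprintf("pos%02d", 1:20),
                       function(b, p) paste0("mm_", p, "_", b)))))
      for (i in seq_len(nrow(sites))) {
        pos <- sites$mismatches[[i]]
        if (!length(pos)) next
        obs <- site_protospacer(g, sites$chrom[i], sites$start[i],
                                sites$strand[i])$protospacer
        for (p in pos) {
          b <- substr(obs, 21L - p, 21L - p)  # genomic base at position p
          mmat[i, paste0("mm_pos", sprintf("%02d", p), "_", b)] <- 1L
        }
      }
    }
    blocks$mismatch <- as.data.frame(mmat)
  }
  if (use_epigenetic) {
    if (length(markers) == 0L) stop("use_epigenetic = TRUE but no markers")
    emat <- vapply(markers, function(m) marker_window_rpm(sites, m),
                   numeric(nrow(sites)))
    emat <- matrix(emat, nrow = nrow(sites))
    colnames(emat) <- vapply(markers, `[[`, "", "name")
    blocks$epigenetic <- as.data.frame(emat)
  }
  do.call(cbind, unname(blocks))
}

#' Train/evaluate an ensemble-of-trees regressor with the published protocol
#'
#' Seeded random 70/30 train/test split; hyperparameters chosen by 5-fold
#' cross-validation (mean squared error) on the training 70%; the selected
#' model is refit on the full training set and evaluated on the held-out 30%.
#' The regressor is pluggable: the default is a random forest
#' ([ranger::ranger()]); any function with signature `function(x, y, params)`
#' returning an object with a `predict(model, x)` method usable via the
#' supplied `predict_fun` can be substituted.
#'
#' @param features data.frame/matrix of predictors.
#' @param targets numeric response (per-site enrichment RPM).
#' @param seed integer seed controlling the split and CV folds.
#' @param grid data.frame of hyperparameter combinations to cross-validate
#'   (default: `num.trees` 300, `mtry` at p/3 and sqrt(p), `min.node.size` 5).
#' @param train_frac training fraction (default 0.70).
#' @param n_folds CV folds (default 5).
#' @param fit_fun,predict_fun pluggable regressor interface.
#' @return list of class `multicut_fit`: `pearson_r_test`, `rmse_test`,
#'   `model`, `best_params`, `train_idx`.
#' @export
fit_eval <- function(features, targets, seed = 1L, grid = NULL,
                     train_frac = 0.70, n_folds = 5L,
                     fit_fun = NULL, predict_fun = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 30L) stop("need at least 30 rows")
  if (sd(targets) == 0) stop("degenerate constant target")
  p <- ncol(features)
  if (is.null(grid)) {
    grid <- expand.grid(num.trees = 300L,
                        mtry = unique(pmax(1L, c(p %/% 3L, floor(sqrt(p))))),
                        min.node.size = 5L)
  }
  if (is.null(fit_fun)) {
    fit_fun <- function(x, y, params) {
      ranger::ranger(x = x, y = y,
                     num.trees = params$num.trees,
                     mtry = min(params$mtry, ncol(x)),
                     min.node.size = params$min.node.size,
                     num.threads = 1L, seed = seed)
    }
    predict_fun <- function(model, x) {
      stats::predict(model, data = x, num.threads = 1L)$predictions
    }
  }
  set.seed(seed)
  train_idx <- sort(sample.int(n, size = floor(train_frac * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  xtr <- features[train_idx, , drop = FALSE]; ytr <- targets[train_idx]
  folds <- sample(rep_len(seq_len(n_folds), length(train_idx)))

  cv_mse <- vapply(seq_len(nrow(grid)), function(gi) {
    params <- grid[gi, , drop = FALSE]
    errs <- vapply(seq_len(n_folds), function(f) {
      hold <- folds == f
      m <- fit_fun(xtr[!hold, , drop = FALSE], ytr[!hold], params)
      pred <- predict_fun(m, xtr[hold, , drop = FALSE])
      mean((pred - ytr[hold])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- grid[which.min(cv_mse), , drop = FALSE]

  model <- fit_fun(xtr, ytr, best)
  pred <- predict_fun(model, features[test_idx, , drop = FALSE])
  ytest <- targets[test_idx]
  structure(list(
    pearson_r_test = cor(pred, ytest),
    rmse_test = sqrt(mean((pred - ytest)^2)),
    model = model, best_params = best, cv_mse = cv_mse,
    train_idx = train_idx, n_test = length(test_idx)
  ), class = "multicut_fit")
}

#' @export
print.multicut_fit <- function(x, ...) {
  cat(sprintf("held-out evaluation: Pearson r = %.3f, RMSE = %.4g (n_test = %d)\n",
              x$pearson_r_test, x$rmse_test, x$n_test))
  invisible(x)
}
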