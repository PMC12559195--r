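# delay-embedded multinomial choice model

#' Delay-embed cues onto a raised-cosine basis
#'
#' Projects the trailing window of each cue onto the basis: the design
#' coefficient for (cue i, basis j) at frame t is
#' `sum_k B[k, j] * cue_i[t - k]` over lags k = 1..L. Frames with
#' incomplete history are dropped, as are frames excluded by `mask`
#' (typically valid courtship frames only).
#'
#' @param cues cue matrix with z-scored cue columns (see [zscore_cues()]);
#'   a `pair` column, if present, is embedded per pair so histories never
#'   cross pair boundaries.
#' @param basis a [cosine_basis()].
#' @param labels optional per-frame labels (factor song/vibration/none)
#'   aligned with `cues` rows, attached as the prediction target.
#' @param mask optional logical row filter applied after embedding.
#' @return An object of class `choice_design`: list with `X` (rows x
#'   (cues*basis) matrix, named `cue|b<j>`), `y` (factor or `NULL`),
#'   `frame`, `cue_names`, `basis`.
#' @export
delay_embed <- function(cues, basis, labels = NULL, mask = NULL) {
  nm <- intersect(cue_names(), names(cues))
  if (length(nm) == 0) {
    abort("no known cue columns present.", class = "courtsig_schema_error")
  }
  L <- basis$n_lags
  pair <- if ("pair" %in% names(cues)) cues$pair else rep(1L, nrow(cues))
  idx_all <- list(); X_all <- list()
  for (p in unique(pair)) {
    rows <- which(pair == p)
    n <- length(rows)
    if (n <= L) next
    Xp <- matrix(NA_real_, n, length(nm) * basis$n_basis)
    for (i in seq_along(nm)) {
      x <- cues[[nm[i]]][rows]
      for (j in seq_len(basis$n_basis)) {
        Xp[, (i - 1) * basis$n_basis + j] <-
          as.numeric(stats::filter(x, c(0, basis$B[, j]), sides = 1))
      }
    }
    keep <- seq.int(L + 1L, n)
    idx_all[[length(idx_all) + 1L]] <- rows[keep]
    X_all[[length(X_all) + 1L]] <- Xp[keep, , drop = FALSE]
  }
  if (length(X_all) == 0) {
    res <- structure(list(X = matrix(0, 0, length(nm) * basis$n_basis),
                          y = NULL, frame = integer(), cue_names = nm,
                          basis = basis, empty = TRUE),
                     class = "choice_design")
    warn("fewer frames than the lag window: empty design.")
    return(res)
  }
  X <- do.call(rbind, X_all)
  idx <- unlist(idx_all)
  colnames(X) <- paste0(rep(nm, each = basis$n_basis), "|b",
                        rep(seq_len(basis$n_basis), length(nm)))
  keep <- rep(TRUE, length(idx))
  if (!is.null(mask)) keep <- keep & mask[idx]
  y <- NULL
  if (!is.null(labels)) {
    lv <- choice_classes()
    y <- factor(as.character(labels)[idx], levels = lv)[keep]
  }
  structure(
    list(X = X[keep, , drop = FALSE], y = y,
         frame = cues$frame[idx][keep], cue_names = nm, basis = basis,
         empty = FALSE),
    class = "choice_design"
  )
}

#' Balance a design by per-class subsampling
#'
#' Randomly subsamples (without replacement) an equal number of rows from
#' each prediction target so song, vibration and no-signal contribute the
#' minimum class count each.
#'
#' @param design a `choice_design` with labels.
#' @param seed integer seed.
#' @param n_per_class rows drawn per class; defaults to the minimum class
#'   count and cannot exceed it.
#' @return A balanced `choice_design`.
#' @export
balance_design <- function(design, seed = 1, n_per_class = NULL) {
  if (is.null(design$y)) {
    abort("design has no labels to balance on.", class = "courtsig_schema_error")
  }
  tab <- table(design$y)
  if (any(tab == 0)) {
    abort(paste0("class absent from design: ",
                 paste(names(tab)[tab == 0], collapse = ", ")),
          class = "courtsig_balance_error")
  }
  m <- min(tab)
  if (!is.null(n_per_class)) {
    if (n_per_class > m) {
      abort("`n_per_class` exceeds the minimum class count.",
            class = "courtsig_balance_error")
    }
    m <- n_per_class
  }
  sel <- withr::with_seed(seed, {
    unlist(lapply(levels(design$y), function(cl) {
      sample(which(design$y == cl), m)
    }))
  })
  sel <- sort(sel)
  design$X <- design$X[sel, , drop = FALSE]
  design$y <- design$y[sel]
  design$frame <- design$frame[sel]
  design
}

default_lambda_grid <- function(n) 10^seq(4, -4, length.out = 10) / n

# one repeat: balance -> split -> cv ridge multinomial -> evaluate
fit_one_repeat <- function(design, folds, max_iter, test_frac, lambda_grid,
                           thresh, n_per_class, seed) {
  bal <- balance_design(design, seed = sub_seed(seed, 1), n_per_class = n_per_class)
  n <- nrow(bal$X)
  test_idx <- withr::with_seed(sub_seed(seed, 2),
                               sample(n, round(test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(length(train_idx))
  converged <- TRUE
  catch_convergence <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("converge|iterations", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  }
  if (length(lambda_grid) >= 2) {
    foldid <- withr::with_seed(sub_seed(seed, 3),
                               sample(rep(seq_len(folds),
                                          length.out = length(train_idx))))
    cv <- catch_convergence(
      glmnet::cv.glmnet(bal$X[train_idx, ], bal$y[train_idx],
                        family = "multinomial", alpha = 0,
                        lambda = lambda_grid, foldid = foldid,
                        standardize = FALSE, maxit = max_iter,
                        thresh = thresh)
    )
    lambda_sel <- cv$lambda.min
    mod <- cv
  } else {
    mod <- catch_convergence(
      glmnet::glmnet(bal$X[train_idx, ], bal$y[train_idx],
                     family = "multinomial", alpha = 0,
                     lambda = lambda_grid, standardize = FALSE,
                     maxit = max_iter, thresh = thresh)
    )
    lambda_sel <- lambda_grid
  }
  pred <- predict(mod, bal$X[test_idx, ], s = lambda_sel, type = "class")
  conf <- confusion_matrix(bal$y[test_idx], factor(pred, levels = levels(bal$y)))
  co <- coef(mod, s = lambda_sel)
  p <- ncol(bal$X)
  W <- vapply(co, function(m) as.numeric(m)[-1], numeric(p))  # p x class
  intercepts <- vapply(co, function(m) as.numeric(m)[1], numeric(1))
  list(weights = W, intercepts = intercepts, lambda = lambda_sel,
       confusion = conf, accuracy = mean(diag(conf$C)), converged = converged,
       n_train = length(train_idx), n_test = length(test_idx))
}

#' Confusion matrix normalized by true class
#'
#' @param truth,pred factors with identical levels.
#' @return List with `C` (rows = true class, normalized to sum 1),
#'   `counts`, and `accuracy` (mean of the diagonal of `C`).
#' @export
confusion_matrix <- function(truth, pred) {
  counts <- table(truth = truth, pred = pred)
  C <- counts / ifelse(rowSums(counts) == 0, NA, rowSums(counts))
  list(C = as.matrix(unclass(C)), counts = as.matrix(unclass(counts)),
       accuracy = mean(diag(as.matrix(unclass(C)))))
}

#' Fit the multinomial choice model
#'
#' Fits an L2-regularized multinomial logistic regression predicting the
#' per-frame choice between song, vibration and no signal from the
#' delay-embedded cues. Each repeat independently rebalances the classes,
#' splits into 90% train / 10% test, selects the regularization strength
#' by 10-fold cross-validation on the training split over a log-spaced
#' grid, and evaluates a true-class-normalized confusion matrix on the
#' held-out test set. Temporal filters are recovered by back-projecting
#' the basis onto the fitted weights, and filter integrals are the sums of
#' the filter values over lags (a positive integral means high cue values
#' promote the signal).
#'
#' @param design a `choice_design` with labels (unbalanced is fine;
#'   balancing happens inside each repeat).
#' @param folds number of CV folds (default 10).
#' @param max_iter maximum fitting iterations (default 500).
#' @param n_repeats number of independent split/balance repeats
#'   (default 10).
#' @param test_frac held-out fraction (default 0.1).
#' @param lambda_grid regularization grid; default 10 log-spaced values.
#' @param thresh glmnet coordinate-descent convergence tolerance.
#' @param n_per_class rows per class after balancing (default: the
#'   minimum class count).
#' @param seed integer root seed.
#' @return An object of class `choice_model_fit`; see [tidy.choice_model_fit()],
#'   [glance.choice_model_fit()], [autoplot.choice_model_fit()].
#' @export
fit_choice_model <- function(design, folds = 10, max_iter = 500,
                             n_repeats = 10, test_frac = 0.1,
                             lambda_grid = NULL, thresh = 1e-4,
                             n_per_class = NULL, seed = 1) {
  if (design$empty || nrow(design$X) == 0) {
    abort("cannot fit on an empty design.", class = "courtsig_config_error")
  }
  reps <- map(seq_len(n_repeats), function(r) {
    fit_one_repeat(design, folds, max_iter, test_frac, lambda_grid,
                   thresh, n_per_class, seed = sub_seed(seed, 100 + r))
  })
  classes <- choice_classes()
  nb <- design$basis$n_basis
  nm <- design$cue_names
  # filters: class x cue x lag, averaged over repeats
  filt_one <- function(W) {
    arr <- array(0, c(length(classes), length(nm), design$basis$n_lags),
                 dimnames = list(classes, nm, NULL))
    for (ci in seq_along(classes)) {
      for (i in seq_along(nm)) {
        w <- W[(i - 1) * nb + seq_len(nb), ci]
        arr[ci, i, ] <- as.numeric(design$basis$B %*% w)
      }
    }
    arr
  }
  filt_list <- map(reps, function(r) filt_one(r$weights))
  filters <- Reduce(`+`, filt_list) / length(filt_list)
  integrals_rep <- map(filt_list, function(a) apply(a, c(1, 2), sum))
  structure(
    list(repeats = reps, filters = filters,
         filter_integrals = apply(filters, c(1, 2), sum),
         integrals_by_repeat = integrals_rep,
         basis = design$basis, cue_names = nm, classes = classes,
         folds = folds, n_repeats = n_repeats, test_frac = test_frac,
         seed = seed),
    class = "choice_model_fit"
  )
}

#' @describeIn fit_choice_model Mean test-set accuracy across repeats.
#' @param fit a `choice_model_fit`.
#' @export
model_accuracy <- function(fit) {
  mean(map_dbl(fit$repeats, "accuracy"))
}

#' Tidy a fitted choice model
#'
#' One row per (class, cue): the filter integral of the repeat-averaged
#' recovered filter.
#'
#' @param x a `choice_model_fit`.
#' @param ... unused.
#' @return A tibble `class`, `cue`, `filter_integral`.
#' @method tidy choice_model_fit
#' @export
tidy.choice_model_fit <- function(x, ...) {
  fi <- x$filter_integrals
  tibble(
    class = rep(rownames(fi), times = ncol(fi)),
    cue = rep(colnames(fi), each = nrow(fi)),
    filter_integral = as.numeric(fi)
  )
}

#' Model-level summary of a fitted choice model
#'
#' @param x a `choice_model_fit`.
#' @param ... unused.
#' @return A one-row tibble: mean/sd accuracy, median selected lambda,
#'   repeats, convergence.
#' @method glance choice_model_fit
#' @export
glance.choice_model_fit <- function(x, ...) {
  acc <- map_dbl(x$repeats, "accuracy")
  tibble(
    accuracy = mean(acc), accuracy_sd = stats::sd(acc),
    lambda = stats::median(map_dbl(x$repeats, "lambda")),
    n_repeats = length(x$repeats),
    all_converged = all(map_dbl(x$repeats, function(r) r$converged) == 1)
  )
}

#' Recovered temporal filters as a long tibble
#'
#' @param fit a `choice_model_fit`.
#' @return A tibble `class`, `cue`, `lag_s`, `value`.
#' @export
model_filters <- function(fit) {
  d <- dim(fit$filters)
  tibble(
    class = rep(fit$classes, times = d[2] * d[3]),
    cue = rep(rep(fit$cue_names, each = d[1]), times = d[3]),
    lag_s = rep(fit$basis$lags_s, each = d[1] * d[2]),
    value = as.numeric(fit$filters)
  )
}

#' @method autoplot choice_model_fit
#' @export
autoplot.choice_model_fit <- function(object, cues = NULL, ...) {
  df <- model_filters(object)
  if (!is.null(cues)) df <- filter(df, .data$cue %in% cues)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$value, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cue, scales = "free_y") +
    ggplot2::labs(x = "lag (s)", y = "filter weight",
                  title = "Recovered temporal filters")
}

#' Per-cue choice models
#'
#' Quantifies the information each cue contributes. In `"restrict"` mode a
#' model is fitted on only the target cue's basis columns; in
#' `"shuffle_others"` mode all columns are kept but every other cue's
#' series is row-permuted before embedding, destroying its temporal
#' relation to the labels.
#'
#' @param cues cue matrix (z-scored).
#' @param labels per-frame labels aligned with `cues`.
#' @param basis a [cosine_basis()].
#' @param mode `"restrict"` (default) or `"shuffle_others"`.
#' @param which_cues cues to evaluate (default: all present).
#' @param mask optional row filter, as in [delay_embed()].
#' @param seed integer seed.
#' @param ... passed to [fit_choice_model()].
#' @return A tibble `cue`, `accuracy`, `fit` (list column of
#'   `choice_model_fit`).
#' @export
per_cue_models <- function(cues, labels, basis,
                           mode = c("restrict", "shuffle_others"),
                           which_cues = NULL, mask = NULL, seed = 1, ...) {
  mode <- match.arg(mode)
  nm <- intersect(cue_names(), names(cues))
  if (is.null(which_cues)) which_cues <- nm
  bad <- setdiff(which_cues, nm)
  if (length(bad)) {
    abort(paste0("unknown cue name: ", paste(bad, collapse = ", ")),
          class = "courtsig_schema_error")
  }
  full_design <- if (mode == "restrict") delay_embed(cues, basis, labels, mask) else NULL
  fits <- map(which_cues, function(cn) {
    if (mode == "restrict") {
      d <- full_design
      cols <- grep(paste0("^", cn, "\\|b"), colnames(d$X))
      d$X <- d$X[, cols, drop = FALSE]
      d$cue_names <- cn
    } else {
      shuffled <- cues
      others <- setdiff(nm, cn)
      perm <- withr::with_seed(sub_seed(seed, 7), sample(nrow(cues)))
      for (oc in others) shuffled[[oc]] <- shuffled[[oc]][perm]
      d <- delay_embed(shuffled, basis, labels, mask)
    }
    fit_choice_model(d, seed = sub_seed(seed, 11), ...)
  })
  tibble(cue = which_cues,
         accuracy = map_dbl(fits, model_accuracy),
         fit = fits)
}
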