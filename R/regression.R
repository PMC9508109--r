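#' Equidistant training-frame selection
#'
#' Picks `M` frame indices evenly spaced over `[1, L]` (first = 1,
#' last = L), rounded to integers; ties after rounding are resolved by
#' moving duplicates to the nearest unused frame.
#'
#' @param L sequence length.
#' @param M number of annotated frames (1 <= M <= L).
#' @return sorted integer vector of length `M`.
#' @export
select_training_frames <- function(L, M) {
  stopifnot(L >= 1)
  if (M < 1 || M > L) stop("select_training_frames: need 1 <= M <= L")
  if (M == 1L) return(1L)
  idx <- round(seq(1, L, length.out = M))
  used <- logical(L)
  out <- integer(M)
  for (k in seq_len(M)) {
    i <- idx[k]
    if (!used[i]) {
      out[k] <- i
    } else {
      # nearest unused frame
      cand <- which(!used)
      out[k] <- cand[which.min(abs(cand - i))]
    }
    used[out[k]] <- TRUE
  }
  sort(out)
}

#' Train per-landmark linear SVR models from sparse annotations
#'
#' For each of the N landmarks, four scalar epsilon-SVR models are trained
#' (u and v in each view) on the same M annotated frames, mapping the
#' concatenated two-view feature vector to the pixel coordinate. Features
#' are standardized channel-wise with training-frame statistics (stored in
#' the model and re-applied at prediction).
#'
#' @param annotations data frame (frame, landmark, view, u, v) covering all
#'   landmarks at every training frame.
#' @param features L x D feature matrix with `frames` giving the frame
#'   index of each row (a [synthesize_features()] result is accepted
#'   directly).
#' @param frames frame indices of the feature rows (defaults to
#'   `features$frames` when `features` is a list).
#' @param C,epsilon SVR hyperparameters (defaults C = 1, epsilon = 0.1 px).
#' @param tol SMO KKT tolerance.
#' @return object of class `landmark_regressor`: list of per-model fits
#'   plus the standardization and hyperparameters.
#' @export
train_landmark_regressors <- function(annotations, features, frames = NULL,
                                      C = 1, epsilon = 0.1, tol = 1e-8) {
  if (is.list(features) && !is.matrix(features)) {
    frames <- features$frames
    features <- features$features
  }
  if (is.null(frames)) frames <- seq_len(nrow(features))
  train_frames <- sort(unique(annotations$frame))
  row_idx <- match(train_frames, frames)
  if (anyNA(row_idx)) {
    stop("train_landmark_regressors: features missing for annotated frame(s) ",
         paste(train_frames[is.na(row_idx)], collapse = ", "))
  }
  Xtr <- features[row_idx, , drop = FALSE]
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Ztr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")

  landmarks <- sort(unique(annotations$landmark))
  views <- sort(unique(annotations$view))
  stopifnot(length(views) == 2L)
  key <- paste(annotations$frame, annotations$landmark, annotations$view)
  models <- list()
  for (lm in landmarks) {
    for (vw in views) {
      idx <- match(paste(train_frames, lm, vw), key)
      if (anyNA(idx)) {
        stop("train_landmark_regressors: missing annotation for landmark '",
             lm, "' view '", vw, "'")
      }
      for (coord in c("u", "v")) {
        y <- annotations[[coord]][idx]
        fit <- train_epsilon_svr(Ztr, y, C = C, epsilon = epsilon, tol = tol)
        models[[paste(lm, vw, coord, sep = "|")]] <-
          list(omega = fit$omega, b = fit$b)
      }
    }
  }
  structure(list(models = models, center = ctr, scale = scl,
                 landmarks = landmarks, views = views,
                 train_frames = train_frames,
                 C = C, epsilon = epsilon, D = ncol(features)),
            class = "landmark_regressor")
}

#' @export
print.landmark_regressor <- function(x, ...) {
  cat("landmark regressor:", length(x$models), "scalar eps-SVR models (",
      length(x$landmarks), "landmarks x", length(x$views), "views x 2 coords),",
      "M =", length(x$train_frames), ", D =", x$D, "\n")
  invisible(x)
}

#' Predict landmark positions for all frames of a sequence
#'
#' @param regressor a `landmark_regressor`.
#' @param features L x D matrix or [synthesize_features()] result.
#' @param frames frame indices of the feature rows.
#' @return data frame (frame, landmark, view, u, v) for every frame,
#'   including the training frames.
#' @export
predict_landmarks <- function(regressor, features, frames = NULL) {
  if (is.list(features) && !is.matrix(features)) {
    frames <- features$frames
    features <- features$features
  }
  if (is.null(frames)) frames <- seq_len(nrow(features))
  if (ncol(features) != length(regressor$center)) {
    stop("predict_landmarks: feature dimension mismatch (got ", ncol(features),
         ", model expects ", length(regressor$center), ")")
  }
  Z <- sweep(sweep(features, 2, regressor$center), 2, regressor$scale, "/")
  out <- list()
  for (lm in regressor$landmarks) {
    for (vw in regressor$views) {
      u <- as.numeric(Z %*% regressor$models[[paste(lm, vw, "u", sep = "|")]]$omega) +
        regressor$models[[paste(lm, vw, "u", sep = "|")]]$b
      v <- as.numeric(Z %*% regressor$models[[paste(lm, vw, "v", sep = "|")]]$omega) +
        regressor$models[[paste(lm, vw, "v", sep = "|")]]$b
      out[[paste(lm, vw)]] <- data.frame(frame = frames, landmark = lm,
                                         view = vw, u = u, v = v,
                                         stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$frame, res$view, res$landmark), , drop = FALSE]
}

#' Localization error against ground truth
#'
#' Root-mean-square pixel error per landmark and view over the common
#' frames, plus a pooled summary row (landmark `"(all)"`).
#'
#' @param predicted,truth observation tables (frame, landmark, view, u, v).
#' @return data frame (landmark, view, rmse_px, n).
#' @export
evaluate_localization <- function(predicted, truth) {
  key_p <- paste(predicted$frame, predicted$landmark, predicted$view)
  key_t <- paste(truth$frame, truth$landmark, truth$view)
  m <- match(key_p, key_t)
  keep <- !is.na(m)
  if (!any(keep)) stop("evaluate_localization: no common (frame, landmark, view)")
  se <- (predicted$u[keep] - truth$u[m[keep]])^2 +
    (predicted$v[keep] - truth$v[m[keep]])^2
  grp <- paste(predicted$landmark[keep], predicted$view[keep], sep = "|")
  ms <- tapply(se, grp, mean)
  ns <- tapply(se, grp, length)
  parts <- strsplit(names(ms), "|", fixed = TRUE)
  out <- data.frame(landmark = vapply(parts, `[`, "", 1L),
                    view = vapply(parts, `[`, "", 2L),
                    rmse_px = sqrt(as.numeric(ms)),
                    n = as.integer(ns), stringsAsFactors = FALSE)
  pooled <- data.frame(landmark = "(all)", view = "(all)",
                       rmse_px = sqrt(mean(se)),
                       n = as.integer(sum(ns)), stringsAsFactors = FALSE)
  rbind(out, pooled)
}

#' Serialize / restore a landmark regressor as JSON
#'
#' @param regressor a `landmark_regressor`.
#' @param path file path.
#' @return `read_regressor_json` returns the regressor.
#' @export
write_regressor_json <- function(regressor, path) {
  jsonlite::write_json(unclass(regressor), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regressor_json
#' @export
read_regressor_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$models <- lapply(obj$models, function(m)
    list(omega = as.numeric(m$omega), b = as.numeric(m$b)))
  structure(obj, class = "landmark_regressor")
}
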