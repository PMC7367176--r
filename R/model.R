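# User-facing model interface: rbpnet() fits a model from bound and unbound
# sequence sets and returns a classed object with the usual methods.

#' Fit a protein-RNA binding model
#'
#' Trains a convolutional + bidirectional-LSTM binary classifier that
#' distinguishes bound (class 1) from unbound (class 0) RNA sequences and
#' emits per-nucleotide binding profiles. By default the data are split
#' 80/10/10 (stratified per class) into training, validation and test sets;
#' the model minimizing binary cross-entropy whose validation AUROC is
#' highest is kept, and its AUROC on the held-out test set is reported.
#'
#' @param pos named character vector (or list) of bound sequences (class 1).
#' @param neg named character vector of unbound sequences (class 0); see
#'   [sample_background()] and [scramble_sequences()] for ways to build one.
#' @param config an [rbpnet_config()]; `...` overrides individual fields.
#' @param validation,test optional explicit hold-out sets, each a list with
#'   `pos` and `neg`; when supplied the 80/10/10 split is skipped.
#' @param ... passed to [rbpnet_config()] when `config` is not supplied.
#' @return an object of class `rbpnet` with elements `params`, `config`,
#'   `history`, `test_auroc`, `metadata`.
#' @examples
#' sim <- simulate_clip(motif_pfm("UGCAUG"), n_pos = 60, n_neg = 60,
#'                      seq_length = 20, seed = 7)
#' fit <- rbpnet(sim$pos, sim$neg, hidden_size = 4, max_epochs = 2, seed = 7)
#' fit
#' predict(fit, sim$pos[1:3])
#' @export
rbpnet <- function(pos, neg, config = NULL, validation = NULL, test = NULL,
                   ...) {
  if (is.null(config)) config <- rbpnet_config(...)
  pos <- as_named_seqs(pos, "pos")
  neg <- as_named_seqs(neg, "neg")
  if (is.null(validation)) {
    sp <- split_train_val_test(pos, neg, seed = config$seed)
    train_set <- sp$train; validation <- sp$validation
    if (is.null(test)) test <- sp$test
  } else {
    train_set <- list(pos = pos, neg = neg)
  }
  as_xy <- function(s) {
    list(sequences = c(s$pos, s$neg),
         labels = c(rep(1, length(s$pos)), rep(0, length(s$neg))))
  }
  config$max_length <- config$max_length %||% max(nchar(c(pos, neg)))
  fit <- train_model(as_xy(train_set), as_xy(validation), config)

  test_auroc <- NA_real_
  if (!is.null(test) && length(test$pos) && length(test$neg)) {
    txy <- as_xy(test)
    te <- encode_tensor(txy$sequences, config$filter_sizes, config$max_length)
    sc <- nn_forward(te$X, te$mask, fit$params)$score
    test_auroc <- auroc(sc, txy$labels)
  }
  structure(list(params = fit$params, config = fit$config,
                 history = fit$history, test_auroc = test_auroc,
                 metadata = list(seed = config$seed,
                                 epochs_run = fit$epochs_run,
                                 best_epoch = fit$best_epoch,
                                 best_metric = fit$best_metric,
                                 selection = config$selection,
                                 n_pos = length(pos), n_neg = length(neg),
                                 fitted = format(Sys.time(), "%Y-%m-%d"))),
            class = "rbpnet")
}

#' @export
print.rbpnet <- function(x, ...) {
  cat("rbpnet model: convolutional BLSTM binding classifier\n")
  cat("  filters:", paste(x$config$filter_sizes, collapse = ","),
      " (one per size) | hidden:", x$config$hidden_size, "per direction\n")
  cat("  max sequence length:", x$config$max_length, "nt\n")
  cat("  trained", x$metadata$epochs_run, "epochs; best epoch",
      x$metadata$best_epoch, "(validation", x$metadata$selection, "=",
      format(x$metadata$best_metric, digits = 4), ")\n")
  if (!is.na(x$test_auroc)) {
    cat("  held-out test AUROC:", format(x$test_auroc, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
summary.rbpnet <- function(object, ...) {
  cat("Model configuration\n")
  cfg <- object$config
  cat("  filter sizes:", paste(cfg$filter_sizes, collapse = ", "),
      "| hidden size:", cfg$hidden_size,
      "| dropout:", cfg$dropout, "\n")
  cat("  ADAM: lr", cfg$learning_rate, "beta1", cfg$beta1, "beta2", cfg$beta2,
      "eps", cfg$eps, "| batch", cfg$batch_size, "\n")
  cat("  selection:", cfg$selection, "| patience:", cfg$patience,
      "| seed:", cfg$seed, "\n\n")
  cat("Training history (last 5 epochs)\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  if (!is.na(object$test_auroc)) {
    cat("\nHeld-out test AUROC:", format(object$test_auroc, digits = 4), "\n")
  }
  invisible(object)
}

#' @export
coef.rbpnet <- function(object, ...) {
  p <- object$params
  list(filters = p$filters,
       fwd = lstm_gates(p$fwd), bwd = lstm_gates(p$bwd),
       output_weight = p$output_weight)
}

#' Predict binding scores or profiles for new sequences
#'
#' @param object a fitted `rbpnet` model.
#' @param newdata named character vector of sequences no longer than the
#'   model's maximum length (use [predict_long()] for longer sequences).
#' @param type `"score"` for a numeric vector of classification scores,
#'   `"profile"` for a list of `binding_profile` objects.
#' @param ... unused.
#' @export
predict.rbpnet <- function(object, newdata, type = c("score", "profile"),
                           ...) {
  type <- match.arg(type)
  newdata <- as_named_seqs(newdata)
  lens <- nchar(newdata)
  if (any(lens > object$config$max_length)) {
    stop("sequence(s) longer than the model maximum (",
         object$config$max_length, " nt): ",
         paste(names(newdata)[lens > object$config$max_length], collapse = ", "),
         "; use predict_long()")
  }
  scores <- numeric(length(newdata))
  profiles <- vector("list", length(newdata))
  chunk <- 512L
  for (start in seq(1L, length(newdata), by = chunk)) {
    take <- start:min(start + chunk - 1L, length(newdata))
    te <- encode_tensor(newdata[take], object$config$filter_sizes,
                        object$config$max_length)
    fw <- nn_forward(te$X, te$mask, object$params)
    scores[take] <- fw$score
    if (type == "profile") {
      for (j in seq_along(take)) {
        vals <- fw$u[j, te$mask[j, ] == 1]
        profiles[[take[j]]] <- structure(
          list(id = te$ids[j], seq = newdata[[take[j]]], values = vals,
               score = fw$score[j]),
          class = "binding_profile")
      }
    }
  }
  if (type == "score") {
    names(scores) <- names(newdata)
    scores
  } else {
    names(profiles) <- names(newdata)
    profiles
  }
}

#' Plot training history of a fitted model
#'
#' @param x a fitted `rbpnet` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rbpnet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_metric, type = "b", pch = 16,
                 xlab = "epoch",
                 ylab = paste("validation", x$config$selection), ...)
  graphics::points(h$epoch[h$best], h$val_metric[h$best], col = "red", pch = 1,
                   cex = 2)
  invisible(x)
}
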