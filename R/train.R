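# Training and cross-validation protocol: k-fold splits (subject-wise, or
# epoch-wise over whole 10-epoch sequence blocks), mini-batches of 5
# sequences, Adam with gradient-norm clipping, periodic testing with
# best-result tracking, and fold-report merging.

#' Training configuration
#'
#' @param batch_sequences sequences per mini-batch (each contributes
#'   `seq_len` epochs).
#' @param seq_len epochs per sequence; must match the model config.
#' @param passes passes over the fold's training sequences.
#' @param eval_every evaluate on the test fold every this many passes.
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip.
#' @param aux_weight auxiliary-loss weight.
#' @param seed seed for initialization, shuffling and dropout.
#' @return A `somnet_train_config` list.
#' @export
train_config <- function(batch_sequences = 5, seq_len = 10, passes = 150,
                         eval_every = 3, lr = 1e-4, clip = 5,
                         aux_weight = 0.5, seed = 42) {
  stopifnot(batch_sequences >= 1, seq_len >= 1, passes >= 1, eval_every >= 1)
  structure(list(batch_sequences = as.integer(batch_sequences),
                 seq_len = as.integer(seq_len), passes = as.integer(passes),
                 eval_every = as.integer(eval_every), lr = lr, clip = clip,
                 aux_weight = aux_weight, seed = as.integer(seed)),
            class = "somnet_train_config")
}

# Non-overlapping sequence blocks in natural temporal order, per subject.
# Returns a tibble: row (position in meta), subject_id, block (global id).
sequence_blocks <- function(meta, seq_len) {
  meta$row <- seq_len(nrow(meta))
  blocks <- meta |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$epoch_index, .by_group = TRUE) |>
    dplyr::mutate(block_in_subject = (dplyr::row_number() - 1) %/% seq_len) |>
    dplyr::ungroup()
  blocks$block <- as.integer(factor(paste(blocks$subject_id,
                                          blocks$block_in_subject)))
  blocks[, c("row", "subject_id", "epoch_index", "block")]
}

#' Assign epochs to cross-validation folds
#'
#' In `subject_wise` mode every epoch of a subject lands in the same fold
#' (with exactly `k` subjects this is leave-one-subject-out). In
#' `epoch_wise` mode whole contiguous `seq_len`-epoch sequence blocks — not
#' single epochs — are dealt to folds, preserving sequence integrity;
#' blocks are shuffled with `seed` before assignment.
#'
#' @param meta tibble with `subject_id` and `epoch_index` (one row per
#'   epoch, aligned with the image batch).
#' @param mode `"subject_wise"` or `"epoch_wise"`.
#' @param k number of folds (default 20).
#' @param seed shuffling seed.
#' @param seq_len sequence length used for epoch-wise blocks.
#' @return `meta` with an integer `fold` column (1..k); attributes `mode`,
#'   `k`.
#' @export
make_folds <- function(meta, mode = c("subject_wise", "epoch_wise"), k = 20,
                       seed = 42, seq_len = 10) {
  mode <- match.arg(mode)
  stopifnot(nrow(meta) > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- tibble::as_tibble(meta)
  if (mode == "subject_wise") {
    subjects <- unique(out$subject_id)
    if (length(subjects) < k) {
      abort(sprintf(paste("Only %d subjects for %d subject-wise folds;",
                          "use k = %d for leave-one-subject-out."),
                    length(subjects), k, length(subjects)),
            class = "somnet_fold_error")
    }
    shuffled <- sample(subjects)
    fold_of <- setNames(rep(seq_len(k), length.out = length(subjects)),
                        shuffled)
    out$fold <- unname(fold_of[out$subject_id])
  } else {
    blocks <- sequence_blocks(out, seq_len)
    ids <- sample(unique(blocks$block))
    fold_of <- setNames(rep(seq_len(k), length.out = length(ids)), ids)
    out$fold <- NA_integer_
    out$fold[blocks$row] <- unname(fold_of[as.character(blocks$block)])
  }
  attr(out, "mode") <- mode
  attr(out, "k") <- k
  out
}

# Training sequences: complete blocks only (remainders dropped).
# Each element: integer vector of seq_len rows into the batch.
training_sequences <- function(meta, seq_len) {
  blocks <- sequence_blocks(meta, seq_len)
  split(blocks$row, blocks$block) |>
    purrr::keep(~ length(.x) == seq_len)
}

# Evaluation sequences: complete blocks, plus one tail-aligned sequence per
# subject covering the remainder; overlapping epochs are scored once (the
# `score` mask marks which positions contribute predictions). Subjects
# shorter than seq_len are right-padded by repeating their last epoch.
evaluation_sequences <- function(meta, seq_len) {
  blocks <- sequence_blocks(meta, seq_len)
  out <- list()
  for (rows in split(blocks$row, blocks$subject_id)) {
    n <- length(rows)
    n_full <- n %/% seq_len
    for (b in seq_len(n_full)) {
      out[[length(out) + 1L]] <-
        list(rows = rows[(b - 1) * seq_len + seq_len(seq_len)],
             score = rep(TRUE, seq_len))
    }
    rem <- n - n_full * seq_len
    if (rem > 0) {
      if (n >= seq_len) {
        idx <- rows[(n - seq_len + 1):n]
        out[[length(out) + 1L]] <-
          list(rows = idx, score = c(rep(FALSE, seq_len - rem),
                                     rep(TRUE, rem)))
      } else {
        idx <- c(rows, rep(rows[n], seq_len - n))
        out[[length(out) + 1L]] <-
          list(rows = idx, score = c(rep(TRUE, n), rep(FALSE, seq_len - n)))
      }
    }
  }
  out
}

adam_update <- function(params, grads, opt, lr, clip,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  opt$t <- opt$t + 1
  bc1 <- 1 - 0.9^opt$t
  bc2 <- 1 - 0.999^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Evaluate a model on a labelled image batch
#'
#' Scores every epoch exactly once: complete sequences plus one
#' tail-aligned sequence per subject whose overlapping epochs are not
#' re-counted. Evaluation mode only (no dropout, no auxiliary head).
#'
#' @param model a `somnet_model`.
#' @param images 76 x 60 x 3 x n array.
#' @param meta tibble aligned with `images`: `subject_id`, `epoch_index`,
#'   `stage`.
#' @param chunk_sequences number of sequences per forward chunk.
#' @return A list: `report` (a `somnet_metrics`), `confusion`, `predicted`
#'   (factor aligned with `meta`).
#' @export
evaluate_model <- function(model, images, meta, chunk_sequences = 16) {
  seq_len_ <- model$cfg$seq_len
  seqs <- evaluation_sequences(meta, seq_len_)
  pred <- rep(NA_character_, nrow(meta))
  for (start in seq(1, length(seqs), by = chunk_sequences)) {
    chunk <- seqs[start:min(start + chunk_sequences - 1, length(seqs))]
    rows <- unlist(lapply(chunk, `[[`, "rows"))
    batch <- images[, , , rows, drop = FALSE]
    out <- predict_stages(model, batch)
    lab <- as.character(out$stage)
    pos <- 0
    for (sq in chunk) {
      take <- which(sq$score)
      pred[sq$rows[take]] <- lab[pos + take]
      pos <- pos + seq_len_
    }
  }
  cm <- confusion(meta$stage, pred)
  list(report = metrics(cm), confusion = cm, predicted = stage_factor(pred))
}

#' Train on one fold and track the best test result
#'
#' Iterates `passes` passes over the training sequences in mini-batches of
#' `batch_sequences` sequences (sequence order reshuffled each pass),
#' optimizing the composite main + auxiliary cross-entropy with Adam.
#' Every `eval_every` passes the model is evaluated on the test fold with
#' the auxiliary head removed and dropout disabled, and the best report
#' (highest ACC, ties broken by MF1) is retained along with its weights.
#'
#' @param train,test lists with `images` (76 x 60 x 3 x n) and `meta`
#'   (tibble `subject_id`, `epoch_index`, `stage`); train and test must be
#'   disjoint.
#' @param tcfg a [train_config()].
#' @param mcfg a [model_config()].
#' @param verbose print per-pass progress.
#' @return A `somnet_fit`: `model` (weights of the best evaluation),
#'   `best` (its `somnet_metrics`), `history` (tibble of per-pass losses
#'   and periodic test metrics), `final_model`.
#' @export
train_fold <- function(train, test, tcfg = train_config(),
                       mcfg = model_config(), verbose = FALSE) {
  if (is.null(train$meta) || nrow(train$meta) == 0 ||
      is.null(test$meta) || nrow(test$meta) == 0) {
    abort("Empty training or test fold.", class = "somnet_value_error")
  }
  stopifnot(tcfg$seq_len == mcfg$seq_len)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  model <- init_model(mcfg, seed = tcfg$seed)
  set.seed(tcfg$seed + 1L)
  train_seqs <- training_sequences(train$meta, tcfg$seq_len)
  if (length(train_seqs) == 0) {
    abort("No complete training sequences.", class = "somnet_value_error")
  }
  opt <- list(m = lapply(model$params, function(p) p * 0),
              v = lapply(model$params, function(p) p * 0), t = 0)

  best <- NULL
  best_params <- NULL
  best_state <- NULL
  hist <- list()
  for (pass in seq_len(tcfg$passes)) {
    ord <- sample(length(train_seqs))
    losses <- c(main = 0, aux = 0, total = 0)
    n_batches <- 0
    for (start in seq(1, length(ord), by = tcfg$batch_sequences)) {
      take <- ord[start:min(start + tcfg$batch_sequences - 1, length(ord))]
      rows <- unlist(train_seqs[take])
      x <- train$images[, , , rows, drop = FALSE]
      y <- one_hot(train$meta$stage[rows], mcfg$n_classes)
      fwd <- model_forward(model, x, training = TRUE)
      model$state <- fwd$state
      loss <- compute_loss(fwd$main_probs, fwd$aux_probs, y, tcfg$aux_weight)
      grads <- model_backward(model, fwd, y)
      up <- adam_update(model$params, grads, opt, tcfg$lr, tcfg$clip)
      model$params <- up$params
      opt <- up$opt
      losses <- losses + c(loss$loss_main, loss$loss_aux, loss$loss_total)
      n_batches <- n_batches + 1
    }
    losses <- losses / n_batches
    row <- tibble::tibble(pass = pass, loss_main = losses[1],
                          loss_aux = losses[2], loss_total = losses[3],
                          test_ACC = NA_real_, test_MF1 = NA_real_,
                          test_kappa = NA_real_)
    if (pass %% tcfg$eval_every == 0 || pass == tcfg$passes) {
      cal <- calibrate_bn(model, train$images)
      ev <- evaluate_model(cal, test$images, test$meta)
      rep_ <- ev$report
      row$test_ACC <- rep_$ACC
      row$test_MF1 <- rep_$MF1
      row$test_kappa <- rep_$kappa
      if (is.null(best) || rep_$ACC > best$ACC ||
          (rep_$ACC == best$ACC && rep_$MF1 > best$MF1)) {
        best <- rep_
        best_params <- cal$params
        best_state <- cal$state
      }
    }
    if (verbose) {
      message(sprintf("pass %3d  loss %.4f%s", pass, losses[3],
                      if (!is.na(row$test_ACC))
                        sprintf("  test ACC %.2f%%", row$test_ACC) else ""))
    }
    hist[[pass]] <- row
  }
  best_model <- model
  best_model$params <- best_params
  best_model$state <- best_state
  structure(list(model = best_model, best = best,
                 history = dplyr::bind_rows(hist), final_model = model,
                 tcfg = tcfg, mcfg = mcfg),
            class = "somnet_fit")
}

#' @export
print.somnet_fit <- function(x, ...) {
  cat(sprintf("<somnet_fit> %d passes; best test ACC %.2f%%, MF1 %.2f%%, kappa %.2f\n",
              nrow(x$history), x$best$ACC, x$best$MF1, x$best$kappa))
  invisible(x)
}

#' @export
tidy.somnet_fit <- function(x, ...) x$history

#' @export
glance.somnet_fit <- function(x, ...) {
  tibble::tibble(ACC = x$best$ACC, MF1 = x$best$MF1, kappa = x$best$kappa,
                 n_test = x$best$n, passes = nrow(x$history),
                 parameters = count_parameters(x$model))
}

#' Cross-validate over pre-assigned folds
#'
#' Trains one model per fold (all other folds form the training set),
#' merges the per-fold test predictions — each epoch is scored exactly once
#' — and reports pooled metrics.
#'
#' @param images full image batch.
#' @param folds output of [make_folds()] (meta with a `fold` column).
#' @param tcfg,mcfg training and model configurations.
#' @param verbose print fold progress.
#' @return A list: `report` (pooled `somnet_metrics`), `confusion`,
#'   `fold_fits` (list of `somnet_fit`).
#' @export
cross_validate <- function(images, folds, tcfg = train_config(),
                           mcfg = model_config(), verbose = FALSE) {
  ks <- sort(unique(folds$fold))
  pred <- rep(NA_character_, nrow(folds))
  fits <- list()
  for (k in ks) {
    tr <- which(folds$fold != k)
    te <- which(folds$fold == k)
    fit <- train_fold(
      list(images = images[, , , tr, drop = FALSE], meta = folds[tr, ]),
      list(images = images[, , , te, drop = FALSE], meta = folds[te, ]),
      tcfg, mcfg, verbose = verbose
    )
    ev <- evaluate_model(fit$model, images[, , , te, drop = FALSE], folds[te, ])
    pred[te] <- as.character(ev$predicted)
    fits[[as.character(k)]] <- fit
  }
  cm <- confusion(folds$stage, pred)
  list(report = metrics(cm), confusion = cm, fold_fits = fits)
}
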