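#' Trial-by-unit spike count matrix with condition labels
#'
#' The common container for all analyses: a numeric matrix of spike counts
#' with one row per stimulus presentation ("trial") and one column per unit,
#' plus per-trial labels for stimulus orientation, attention condition, the
#' subject's choice (optional), and session block (optional).
#'
#' @param counts Numeric matrix, trials x units; finite, typically
#'   nonnegative spike counts.
#' @param theta Numeric vector of per-trial orientations on the normalized
#'   ring `[0, 1)`, or `NA` when undefined.
#' @param attention Per-trial attention labels (factor/character/numeric);
#'   defaults to a single condition.
#' @param choice Optional per-trial binary choice label (1 = saccade/"change",
#'   0 = no saccade).
#' @param block Optional per-trial block identifier.
#' @param window Optional character descriptor of the counting window, e.g.
#'   `"60-130ms"`; carried as metadata so analyses can assert they were fed
#'   counts from the intended window.
#' @return An object of class `trial_matrix`.
#' @examples
#' tm <- trial_matrix(matrix(rpois(40, 5), 10, 4), theta = rep(0.5, 10))
#' dim(tm)
#' summary(tm)
#' @export
trial_matrix <- function(counts, theta = NULL, attention = NULL,
                         choice = NULL, block = NULL, window = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  stop_if_not_finite(counts, "counts")
  if (is.null(theta)) theta <- rep(NA_real_, n)
  if (is.null(attention)) attention <- rep("none", n)
  if (length(theta) != n || length(attention) != n) {
    stop("label vectors must have one entry per trial (row of 'counts')")
  }
  if (!is.null(choice) && length(choice) != n) {
    stop("'choice' must have one entry per trial")
  }
  if (!is.null(block) && length(block) != n) {
    stop("'block' must have one entry per trial")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("unit_%d", seq_len(ncol(counts)) - 1L)
  }
  structure(
    list(counts = counts, theta = as.numeric(theta),
         attention = as.character(attention),
         choice = if (is.null(choice)) NULL else as.integer(choice),
         block = block, window = window),
    class = "trial_matrix"
  )
}

#' @export
dim.trial_matrix <- function(x) dim(x$counts)

#' Number of trials / units in a trial matrix
#' @param x A `trial_matrix`.
#' @return Integer count.
#' @export
n_trials <- function(x) nrow(x$counts)

#' @rdname n_trials
#' @export
n_units <- function(x) ncol(x$counts)

#' @export
print.trial_matrix <- function(x, ...) {
  nt <- n_trials(x); nu <- n_units(x)
  cat(sprintf("trial_matrix: %d trials x %d units\n", nt, nu))
  th <- unique(round(x$theta[!is.na(x$theta)], 6))
  cat(sprintf("  orientations: %d distinct on [0,1)\n", length(th)))
  cat(sprintf("  attention conditions: %s\n",
              paste(unique(x$attention), collapse = ", ")))
  if (!is.null(x$choice)) {
    cat(sprintf("  choices: %d saccade / %d no-saccade\n",
                sum(x$choice == 1L), sum(x$choice == 0L)))
  }
  if (!is.null(x$window)) cat(sprintf("  counting window: %s\n", x$window))
  invisible(x)
}

#' @export
summary.trial_matrix <- function(object, ...) {
  m <- colMeans(object$counts)
  out <- list(
    n_trials = n_trials(object), n_units = n_units(object),
    mean_count = mean(m), count_range = range(object$counts),
    orientations = sort(unique(object$theta[!is.na(object$theta)])),
    attention = table(object$attention)
  )
  class(out) <- "summary.trial_matrix"
  out
}

#' @export
print.summary.trial_matrix <- function(x, ...) {
  cat(sprintf("trial_matrix: %d trials x %d units, mean count %.3f\n",
              x$n_trials, x$n_units, x$mean_count))
  cat(sprintf("  count range [%g, %g]; %d orientations\n",
              x$count_range[1], x$count_range[2], length(x$orientations)))
  print(x$attention)
  invisible(x)
}

#' Subset trials of a trial matrix
#'
#' @param x A `trial_matrix`.
#' @param trials Row index (logical/integer) over trials.
#' @param units Optional column index over units.
#' @return A `trial_matrix` with the selected trials/units.
#' @export
subset_trials <- function(x, trials, units = NULL) {
  if (is.null(units)) units <- seq_len(n_units(x))
  trial_matrix(
    x$counts[trials, units, drop = FALSE],
    theta = x$theta[trials],
    attention = x$attention[trials],
    choice = if (is.null(x$choice)) NULL else x$choice[trials],
    block = if (is.null(x$block)) NULL else x$block[trials],
    window = x$window
  )
}

#' Bind trial matrices over trials
#' @param ... `trial_matrix` objects with identical unit counts.
#' @return A combined `trial_matrix`.
#' @export
rbind_trials <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1)
  trial_matrix(
    do.call(rbind, lapply(xs, `[[`, "counts")),
    theta = unlist(lapply(xs, `[[`, "theta")),
    attention = unlist(lapply(xs, `[[`, "attention")),
    choice = if (all(vapply(xs, function(x) !is.null(x$choice), TRUE)))
      unlist(lapply(xs, `[[`, "choice")) else NULL,
    block = if (all(vapply(xs, function(x) !is.null(x$block), TRUE)))
      unlist(lapply(xs, `[[`, "block")) else NULL,
    window = xs[[1]]$window
  )
}

#' @export
as.data.frame.trial_matrix <- function(x, ...) {
  df <- as.data.frame(x$counts)
  df$theta <- x$theta
  df$attention <- x$attention
  df$choice <- if (is.null(x$choice)) NA_integer_ else x$choice
  df$block <- if (is.null(x$block)) NA else x$block
  df
}

#' Write / read a trial matrix as columnar CSV
#'
#' One row per trial; unit count columns `unit_0..unit_{N-1}` followed by
#' `theta`, `attention`, `choice`, `block`.
#'
#' @param x A `trial_matrix`.
#' @param path File path.
#' @return `write_trial_matrix` returns `path` invisibly;
#'   `read_trial_matrix` returns a `trial_matrix`.
#' @export
write_trial_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_matrix
#' @export
read_trial_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit_cols <- grep("^unit_", names(df), value = TRUE)
  choice <- if (all(is.na(df$choice))) NULL else df$choice
  block <- if (all(is.na(df$block))) NULL else df$block
  trial_matrix(as.matrix(df[, unit_cols, drop = FALSE]),
               theta = df$theta, attention = df$attention,
               choice = choice, block = block)
}

# split trial indices by (theta, attention) condition cells
condition_cells <- function(x) {
  key <- paste(signif(x$theta, 12), x$attention, sep = "|")
  split(seq_len(n_trials(x)), key)
}
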