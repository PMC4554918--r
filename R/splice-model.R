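# Donor-window extraction and splice-donor strength models. A donor window
# is nine bases: the last three exonic bases followed by the first six
# intron-side bases, so the candidate GT occupies window positions 4-5.
# Models score windows in bits as log2(P_model / P_background).

#' Coerce donor windows to a canonical tibble
#'
#' @param x Character vector of windows, or a tibble with a `window` column.
#' @return Tibble with columns `window` and `valid` (`FALSE` when the
#'   window contains `N` or other non-ACGT characters; such windows are
#'   flagged rather than scored).
#' @export
as_donor_windows <- function(x) {
  if (is.data.frame(x)) {
    if (!"window" %in% names(x)) abort("expected a 'window' column")
    out <- as_tibble(x)
  } else {
    out <- tibble(window = as.character(x))
  }
  out$window <- toupper(out$window)
  out$valid <- !grepl("[^ACGT]", out$window)
  out
}

#' Extract the nine-base donor window at a cut site
#'
#' The window is the last three retained exonic bases plus the next six
#' bases, drawn first from the exon remainder beyond the cut and then from
#' the downstream flank (intron). For a terminal donor (`cut` equal to the
#' exon length) all six right-side bases come from the flank.
#'
#' @param exon_seq Sense-strand exon sequence.
#' @param downstream_flank Sense-strand sequence following the exon.
#' @param cut Retained-length cut index (the donor's GT begins at 0-based
#'   exon position `cut`, or at the first flank base when `cut` equals the
#'   exon length).
#' @param gene_id,exon_label Optional provenance, carried into the output.
#' @return One-row tibble: `gene_id`, `exon_label`, `cut_index`, `window`,
#'   `valid`.
#' @export
#' @examples
#' extract_donor_window("TTTACG", "GTAAGTCC", cut = 6)
extract_donor_window <- function(exon_seq, downstream_flank = "", cut,
                                 gene_id = NA_character_,
                                 exon_label = NA_character_) {
  exon_seq <- toupper(exon_seq); downstream_flank <- toupper(downstream_flank)
  cut <- as.integer(cut)
  L <- nchar(exon_seq)
  if (cut < 3) {
    abort(sprintf("cut %d leaves fewer than 3 exonic bases on the left", cut))
  }
  if (cut > L) abort(sprintf("cut %d exceeds exon length %d", cut, L))
  right <- paste0(substr0(exon_seq, cut, L), downstream_flank)
  if (nchar(right) < 6) {
    abort(sprintf(
      "only %d bases available right of the cut (need 6); supply more downstream flank",
      nchar(right)
    ))
  }
  win <- paste0(substr0(exon_seq, cut - 3L, cut), substr0(right, 0L, 6L))
  tibble(gene_id = gene_id, exon_label = exon_label, cut_index = cut,
         window = win, valid = !grepl("[^ACGT]", win))
}

#' Read / write a validated-donor list
#'
#' TSV with columns `gene_id`, `exon_label`, `cut_index`, `window`.
#'
#' @param path File path.
#' @return `read_donor_windows()`: tibble with a `valid` column added.
#' @export
read_donor_windows <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  as_donor_windows(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_donor_windows
#' @param x Donor-window tibble.
#' @export
write_donor_windows <- function(x, path) {
  readr::write_tsv(select(as_tibble(x), -dplyr::any_of("valid")), path)
  invisible(path)
}

new_splice_model <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("<splice_model> kind=%s, window length %d, trained on n=%s\n",
              x$kind, x$length %||% NA_integer_,
              format(x$n %||% NA)))
  invisible(x)
}

# windows tibble -> integer matrix of base codes (A=1,C=2,G=3,T=4),
# valid rows only; checks a uniform length.
window_matrix <- function(w) {
  wv <- w$window[w$valid]
  if (length(wv) == 0) abort("no valid (ACGT-only) windows")
  Ls <- unique(nchar(wv))
  if (length(Ls) != 1) abort("windows have differing lengths")
  m <- matrix(match(unlist(strsplit(wv, "")), BASES), ncol = Ls, byrow = TRUE)
  m
}

#' Train a position weight matrix donor model
#'
#' Per-position base frequencies with additive smoothing:
#' `(count + alpha) / (n + 4 alpha)`.
#'
#' @param windows Donor windows ([as_donor_windows()] input). Windows
#'   containing `N` are excluded from training.
#' @param pseudocount Additive pseudocount `alpha` per base and position.
#' @param background Background base-frequency vector (A, C, G, T); used as
#'   the default scoring background.
#' @return A `splice_model` of kind `"pwm"`.
#' @export
train_pwm <- function(windows, pseudocount = 0.5,
                      background = c(0.25, 0.25, 0.25, 0.25)) {
  w <- as_donor_windows(windows)
  m <- window_matrix(w)
  n <- nrow(m); L <- ncol(m)
  counts <- t(apply(m, 2, tabulate, nbins = 4))
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(probs) <- list(NULL, BASES)
  new_splice_model("pwm", list(
    probs = probs, background = background, pseudocount = pseudocount,
    n = n, length = L
  ))
}

default_maxent_constraints <- function(L) {
  c(as.list(seq_len(L)),
    purrr::map(seq_len(L - 1), function(i) c(i, i + 1L)))
}

constraint_index <- function(m, cons) {
  # linear index (1-based) of the bases at positions `cons` in each row
  k <- length(cons)
  idx <- rep(0L, nrow(m))
  for (j in seq_len(k)) idx <- idx * 4L + (m[, cons[j]] - 1L)
  idx + 1L
}

#' Train a maximum-entropy donor model
#'
#' Fits, by iterative proportional fitting (IPF), the maximum-entropy
#' distribution over all windows whose declared marginals equal the
#' pseudocounted empirical marginals of the training windows. Pseudocounts
#' are applied as `4 * pseudocount` uniform pseudo-windows, which keeps the
#' marginal targets mutually consistent and makes the singleton targets
#' identical to [train_pwm()]'s frequencies. The model stores one factor
#' table per constraint, not the full joint table; fitting enumerates the
#' `4^L` window space internally, which is practical for the nine-base
#' donor windows used here.
#'
#' @inheritParams train_pwm
#' @param constraints List of integer vectors of 1-based window positions
#'   whose joint marginals are constrained. Must include every singleton.
#'   Default: all singletons plus adjacent pairs.
#' @param tol Convergence tolerance on the maximum absolute marginal
#'   discrepancy.
#' @param max_iter Maximum IPF sweeps.
#' @return A `splice_model` of kind `"maxent"`.
#' @export
train_maxent <- function(windows, constraints = NULL, pseudocount = 0.5,
                         background = c(0.25, 0.25, 0.25, 0.25),
                         tol = 1e-8, max_iter = 1000) {
  w <- as_donor_windows(windows)
  m <- window_matrix(w)
  n <- nrow(m); L <- ncol(m)
  if (L > 10) abort("maxent fitting enumerates 4^L windows; L > 10 unsupported")
  if (is.null(constraints)) constraints <- default_maxent_constraints(L)
  constraints <- purrr::map(constraints, as.integer)
  singles <- purrr::map_int(keep(constraints, ~ length(.x) == 1), ~ .x)
  if (!setequal(singles, seq_len(L))) {
    abort("constraints must include every singleton position")
  }
  if (any(purrr::map_lgl(constraints, ~ any(.x < 1 | .x > L)))) {
    abort("constraint positions out of range")
  }

  pseudo <- 4 * pseudocount  # uniform pseudo-windows
  targets <- purrr::map(constraints, function(cons) {
    k <- length(cons)
    idx <- constraint_index(m, cons)
    cnt <- tabulate(idx, nbins = 4^k)
    (cnt + pseudo / 4^k) / (n + pseudo)
  })

  # enumerate the window space: rows of `grid` are base codes per position
  M <- 4^L
  grid <- matrix(0L, nrow = M, ncol = L)
  for (j in seq_len(L)) {
    grid[, j] <- ((seq_len(M) - 1L) %/% 4^(L - j)) %% 4L + 1L
  }
  cons_idx <- purrr::map(constraints, function(cons) constraint_index(grid, cons))

  p <- rep(1 / M, M)
  factors <- purrr::map(constraints, function(cons) rep(1, 4^length(cons)))
  converged <- FALSE
  worst <- NA_real_; worst_c <- NA_integer_
  for (iter in seq_len(max_iter)) {
    worst <- 0; worst_c <- 1L
    for (ci in seq_along(constraints)) {
      idx <- cons_idx[[ci]]
      marg <- numeric(length(targets[[ci]]))
      tmp <- rowsum(p, idx)
      marg[as.integer(rownames(tmp))] <- tmp[, 1]
      disc <- max(abs(marg - targets[[ci]]))
      if (disc > worst) { worst <- disc; worst_c <- ci }
      ratio <- ifelse(marg > 0, targets[[ci]] / marg, 1)
      p <- p * ratio[idx]
      factors[[ci]] <- factors[[ci]] * ratio
    }
    if (worst < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(
      "IPF did not converge in %d sweeps; worst constraint [%s], discrepancy %.3g",
      max_iter, paste(constraints[[worst_c]], collapse = ","), worst
    ))
  }
  log2_norm <- log2(sum(p))  # ~0; folds residual mass into the score
  new_splice_model("maxent", list(
    factors = factors, constraints = constraints,
    singleton_probs = {
      sp <- do.call(rbind, targets[purrr::map_lgl(constraints, ~ length(.x) == 1)][
        order(singles)])
      dimnames(sp) <- list(NULL, BASES); sp
    },
    background = background, pseudocount = pseudocount,
    n = n, length = L, tol = tol, log2_norm = log2_norm
  ))
}

#' Load a precomputed per-window score table model
#'
#' A `table` model carries externally produced scores (for example a
#' published donor-site score table supplied by the user) keyed by window
#' sequence; [score_windows()] then returns the stored score directly.
#'
#' @param scores Named numeric vector (names are window sequences) or a
#'   tibble with columns `window` and `score`.
#' @return A `splice_model` of kind `"table"`.
#' @export
table_model <- function(scores) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, toupper(scores$window))
  }
  L <- unique(nchar(names(scores)))
  if (length(L) != 1) abort("table model windows must share one length")
  new_splice_model("table", list(table = scores, length = L, n = length(scores)))
}

#' Attach a decoy background model
#'
#' When a decoy model is attached, [score_windows()] reports
#' `log2(P_model / P_decoy)` instead of scoring against the independent
#' base-frequency background.
#'
#' @param model,decoy `splice_model` objects of matching window length.
#' @return `model` with the decoy attached.
#' @export
attach_decoy <- function(model, decoy) {
  if (!inherits(decoy, "splice_model")) abort("decoy must be a splice_model")
  if (!is.null(model$length) && !is.null(decoy$length) &&
      model$length != decoy$length) {
    abort("decoy window length differs from model")
  }
  model$decoy <- decoy
  model
}

# log2 model probability for a base-code matrix (rows = windows)
log2_prob <- function(model, m) {
  switch(model$kind,
    pwm = {
      lp <- log2(model$probs)
      rowSums(matrix(lp[cbind(rep(seq_len(ncol(m)), each = nrow(m)),
                              as.vector(m))],
                     nrow = nrow(m)))
    },
    maxent = {
      s <- rep(-2 * model$length - model$log2_norm, nrow(m))
      for (ci in seq_along(model$constraints)) {
        idx <- constraint_index(m, model$constraints[[ci]])
        s <- s + log2(model$factors[[ci]][idx])
      }
      s
    },
    abort(sprintf("cannot compute probabilities for a '%s' model", model$kind))
  )
}

#' Score donor windows in bits
#'
#' For `pwm` and `maxent` models the score is
#' `log2(P_model(window) / P_background(window))`, with the background an
#' independent base-frequency model unless a decoy model has been attached
#' (see [attach_decoy()]). For `table` models the stored score is returned.
#' Windows containing `N` are not scored: they get `NA` with `valid =
#' FALSE`.
#'
#' @param model A `splice_model`.
#' @param windows Donor windows ([as_donor_windows()] input).
#' @return The windows tibble with a `score` column (bits) added.
#' @export
score_windows <- function(model, windows) {
  w <- as_donor_windows(windows)
  w$score <- NA_real_
  ok <- which(w$valid)
  if (length(ok) == 0) return(w)
  if (any(nchar(w$window[ok]) != model$length)) {
    abort(sprintf("windows must have length %d for this model", model$length))
  }
  if (model$kind == "table") {
    w$score[ok] <- unname(model$table[w$window[ok]])
    return(w)
  }
  m <- matrix(match(unlist(strsplit(w$window[ok], "")), BASES),
              ncol = model$length, byrow = TRUE)
  lp <- log2_prob(model, m)
  if (!is.null(model$decoy)) {
    lb <- log2_prob(model$decoy, m)
  } else {
    bg <- model$background
    lb <- rowSums(matrix(log2(bg)[as.vector(m)], nrow = nrow(m)))
  }
  w$score[ok] <- lp - lb
  w
}

#' @rdname score_windows
#' @param window A single window string.
#' @return `score_window()`: a single numeric score.
#' @export
score_window <- function(model, window) {
  score_windows(model, window)$score[1]
}

#' Mean and standard deviation of validated donor scores
#'
#' Summarises a gene's validated splice donors under a model, giving the
#' reference distribution cryptic-site candidates are compared against.
#'
#' @inheritParams score_windows
#' @param windows At least two valid donor windows.
#' @return One-row tibble: `mean` (bits), `sd` (sample SD, n-1), `n`.
#' @export
donor_score_stats <- function(windows, model) {
  scored <- score_windows(model, windows)
  s <- scored$score[scored$valid]
  if (length(s) < 2) abort("need at least 2 valid windows for mean and SD")
  tibble(mean = mean(s), sd = stats::sd(s), n = length(s))
}

#' @export
tidy.splice_model <- function(x, ...) {
  probs <- switch(x$kind,
    pwm = x$probs,
    maxent = x$singleton_probs,
    abort("tidy() is defined for pwm and maxent models")
  )
  as_tibble(probs) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(all_of(BASES), names_to = "base", values_to = "freq") |>
    select(all_of(c("position", "base", "freq")))
}

#' @export
glance.splice_model <- function(x, ...) {
  tibble(kind = x$kind, window_length = x$length %||% NA_integer_,
         n_train = x$n %||% NA_integer_,
         pseudocount = x$pseudocount %||% NA_real_,
         n_constraints = if (x$kind == "maxent") length(x$constraints) else NA_integer_)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a splice model
#'
#' Plain-text serialisation that round-trips bit-exactly. PWM models store
#' the position-by-base frequency table; maxent models store the
#' constraint list and fitted factor tables; table models store the
#' window-to-score map.
#'
#' @param model A `splice_model`.
#' @param path File path.
#' @return `read_splice_model()`: the model; `write_splice_model()`:
#'   `path`, invisibly.
#' @export
write_splice_model <- function(model, path) {
  ln <- c(sprintf("#kind\t%s", model$kind),
          sprintf("#length\t%d", model$length))
  if (!is.null(model$n)) ln <- c(ln, sprintf("#n\t%d", model$n))
  if (!is.null(model$pseudocount)) {
    ln <- c(ln, sprintf("#pseudocount\t%s", fmt_num(model$pseudocount)))
  }
  if (!is.null(model$background)) {
    ln <- c(ln, sprintf("#background\t%s",
                        paste(fmt_num(model$background), collapse = "\t")))
  }
  if (model$kind == "pwm") {
    ln <- c(ln, apply(model$probs, 1, function(r) paste(fmt_num(r), collapse = "\t")))
  } else if (model$kind == "maxent") {
    ln <- c(ln, sprintf("#log2_norm\t%s", fmt_num(model$log2_norm)))
    for (ci in seq_along(model$constraints)) {
      ln <- c(ln, sprintf("constraint\t%s\t%s",
                          paste(model$constraints[[ci]], collapse = ","),
                          paste(fmt_num(model$factors[[ci]]), collapse = "\t")))
    }
    ln <- c(ln, sprintf("#singleton_probs\t%s",
                        paste(fmt_num(as.vector(model$singleton_probs)),
                              collapse = "\t")))
  } else if (model$kind == "table") {
    ln <- c(ln, sprintf("%s\t%s", names(model$table), fmt_num(model$table)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_splice_model
#' @export
read_splice_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  get <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(h) == 0) return(NULL)
    strsplit(sub(paste0("^#", key, "\t"), "", h[1]), "\t")[[1]]
  }
  kind <- get("kind")
  L <- as.integer(get("length"))
  fields <- list(length = L)
  if (!is.null(get("n"))) fields$n <- as.integer(get("n"))
  if (!is.null(get("pseudocount"))) fields$pseudocount <- as.numeric(get("pseudocount"))
  if (!is.null(get("background"))) fields$background <- as.numeric(get("background"))
  if (kind == "pwm") {
    probs <- do.call(rbind, purrr::map(body, ~ as.numeric(strsplit(.x, "\t")[[1]])))
    dimnames(probs) <- list(NULL, BASES)
    fields$probs <- probs
  } else if (kind == "maxent") {
    fields$log2_norm <- as.numeric(get("log2_norm"))
    cons <- list(); facs <- list()
    for (b in body) {
      f <- strsplit(b, "\t")[[1]]
      if (f[1] != "constraint") next
      cons[[length(cons) + 1]] <- as.integer(strsplit(f[2], ",")[[1]])
      facs[[length(facs) + 1]] <- as.numeric(f[-(1:2)])
    }
    fields$constraints <- cons
    fields$factors <- facs
    sp <- matrix(as.numeric(get("singleton_probs")), ncol = 4)
    dimnames(sp) <- list(NULL, BASES)
    fields$singleton_probs <- sp
  } else if (kind == "table") {
    parts <- strsplit(body, "\t")
    fields$table <- stats::setNames(
      as.numeric(purrr::map_chr(parts, 2)), purrr::map_chr(parts, 1)
    )
    fields$n <- length(fields$table)
  } else {
    abort(sprintf("unknown model kind '%s'", kind))
  }
  new_splice_model(kind, fields)
}
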