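#' Synthetic posture-feature profiles
#'
#' A profile describes how to draw silhouette features for one pose class:
#' per feature, the linguistic label(s) whose full-membership core the
#' samples should occupy.  When several labels are listed for a feature
#' (a disjunctive profile such as `Lo` or `Me` spread for the lying pose),
#' one is chosen uniformly per sample.  Gaussian noise with standard
#' deviation `noise_scale` times the label's support width is added, and a
#' `mislabel_rate` fraction of the class's samples is flipped to the other
#' class to create realistic overlap.
#'
#' The default profiles mirror the most relevant attribute values of the two
#' crisp pose concepts: lying frames are low and flat
#' (`hw` Lo, `hmax` Lo, `sigma` Lo or Me, `p40` Hi), upright frames tall and
#' narrow (`hw` Hi or Me, `hmax` Hi, `sigma` Lo, `p40` Lo).
#'
#' @param class_label `"isLy"` or `"notLy"`.
#' @param labels named list: per feature, a character vector of target
#'   labels.
#' @param noise_scale positive noise multiplier (default 0.15).
#' @param mislabel_rate class-flip fraction in `[0, 0.5)` (default 0.02).
#' @return an object of class `synth_profile`.
#' @export
synth_profile <- function(class_label, labels, noise_scale = 0.15,
                          mislabel_rate = 0.02) {
  stopifnot(is.character(class_label), length(class_label) == 1L,
            is.list(labels), length(labels) > 0L)
  if (!is.numeric(noise_scale) || noise_scale <= 0)
    stop("'noise_scale' must be positive", call. = FALSE)
  if (!is.numeric(mislabel_rate) || mislabel_rate < 0 || mislabel_rate >= 0.5)
    stop("'mislabel_rate' must lie in [0, 0.5)", call. = FALSE)
  structure(list(class_label = class_label,
                 labels = lapply(labels, as.character),
                 noise_scale = noise_scale,
                 mislabel_rate = mislabel_rate),
            class = "synth_profile")
}

#' @rdname synth_profile
#' @export
default_synth_profiles <- function(noise_scale = 0.15,
                                   mislabel_rate = 0.02) {
  list(
    isLy = synth_profile("isLy",
      list(hw = "Lo", hmax = "Lo", sigma = c("Lo", "Me"), p40 = "Hi"),
      noise_scale, mislabel_rate),
    notLy = synth_profile("notLy",
      list(hw = c("Hi", "Me"), hmax = "Hi", sigma = "Lo", p40 = "Lo"),
      noise_scale, mislabel_rate))
}

# full-membership core and support width of a label curve on its universe
mf_core <- function(mf, universe) {
  switch(mf$kind,
    z = list(core = c(universe[1], mf$a), width = mf$b - mf$a),
    s = list(core = c(mf$b, universe[2]), width = mf$b - mf$a),
    gauss2 = list(core = c(mf$c1, mf$c2),
                  width = mf$sigma1 + mf$sigma2))
}

#' Generate a labelled synthetic feature table
#'
#' Draws `n_per_class` frames per pose class from the given profiles:
#' uniformly inside the full-membership core of each target label, plus
#' Gaussian noise scaled by the label's support width, clamped to the
#' feature universe.  A fixed seed makes the table reproducible.
#'
#' @param n_per_class frames per class (0 gives an empty table).
#' @param profiles named list of [synth_profile()]s
#'   (default [default_synth_profiles()]).
#' @param variables linguistic variables (default [posture_variables()]).
#' @param seed optional integer seed.
#' @return data.frame with the feature columns and a `label` column.
#' @export
#' @examples
#' head(synth_generate(5, seed = 1))
synth_generate <- function(n_per_class,
                           profiles = default_synth_profiles(),
                           variables = posture_variables(),
                           seed = NULL) {
  stopifnot(n_per_class >= 0)
  if (!is.null(seed)) set.seed(seed)
  feats <- names(profiles[[1L]]$labels)
  empty <- stats::setNames(
    as.data.frame(c(rep(list(numeric(0)), length(feats)),
                    list(character(0)))), c(feats, "label"))
  if (n_per_class == 0L) return(empty)
  chunks <- lapply(profiles, function(pf) {
    bad <- setdiff(names(pf$labels), names(variables))
    if (length(bad))
      stop("profile targets unknown feature(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    cols <- lapply(names(pf$labels), function(f) {
      v <- variables[[f]]
      opts <- pf$labels[[f]]
      bad_lab <- setdiff(opts, names(v$labels))
      if (length(bad_lab))
        stop("invalid label(s) for feature '", f, "': ",
             paste(bad_lab, collapse = ", "), call. = FALSE)
      pick <- sample(opts, n_per_class, replace = TRUE)
      x <- numeric(n_per_class)
      for (lab in unique(pick)) {
        i <- which(pick == lab)
        geom <- mf_core(v$labels[[lab]], v$universe)
        x[i] <- stats::runif(length(i), geom$core[1], geom$core[2]) +
          stats::rnorm(length(i), 0, pf$noise_scale * geom$width)
      }
      pmin(pmax(x, v$universe[1]), v$universe[2])
    })
    names(cols) <- names(pf$labels)
    df <- as.data.frame(cols)
    df$label <- rep(pf$class_label, n_per_class)
    n_flip <- round(pf$mislabel_rate * n_per_class)
    if (n_flip > 0L) {
      other <- setdiff(vapply(profiles, `[[`, character(1), "class_label"),
                       pf$class_label)[1L]
      df$label[sample.int(n_per_class, n_flip)] <- other
    }
    df
  })
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}
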