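#' Jujube defect label vocabulary
#'
#' The eight-label vocabulary used throughout the package. The order is fixed
#' and defines the index of every multi-hot target vector and of every
#' label-wise feature channel.
#'
#' @return Character vector of the eight label codes: `n` (normal),
#'   `r` (russeting), `mr` (mild rot), `sr` (severe rot), `c` (cracking),
#'   `s` (shriveled), `p` (peeling), `bp` (bird pecking).
#' @export
#' @examples
#' jujube_labels()
jujube_labels <- function() {
  c("n", "r", "mr", "sr", "c", "s", "p", "bp")
}

#' Full names of the jujube defect labels
#'
#' @return Named character vector mapping label codes to descriptive names.
#' @export
jujube_label_names <- function() {
  c(n = "normal", r = "russeting", mr = "mild rot", sr = "severe rot",
    c = "cracking", s = "shriveled", p = "peeling", bp = "bird pecking")
}

# The dataset census: 18 label combinations with their sample counts.
# Singles sum to 660, doubles to 1200, triples to 70; grand total 1930.
default_combos <- function() {
  list(
    list(labels = "n",                    count = 100L),
    list(labels = "r",                    count = 80L),
    list(labels = "mr",                   count = 80L),
    list(labels = "sr",                   count = 80L),
    list(labels = "c",                    count = 80L),
    list(labels = "s",                    count = 80L),
    list(labels = "p",                    count = 80L),
    list(labels = "bp",                   count = 80L),
    list(labels = c("r", "p"),            count = 200L),
    list(labels = c("r", "c"),            count = 200L),
    list(labels = c("mr", "p"),           count = 200L),
    list(labels = c("mr", "c"),           count = 200L),
    list(labels = c("bp", "p"),           count = 200L),
    list(labels = c("s", "p"),            count = 200L),
    list(labels = c("r", "p", "mr"),      count = 20L),
    list(labels = c("r", "p", "c"),       count = 20L),
    list(labels = c("mr", "c", "p"),      count = 15L),
    list(labels = c("bp", "sr", "c"),     count = 15L)
  )
}

#' Default per-label motif rendering parameters
#'
#' Each defect label is rendered as a geometrically distinct, locally confined
#' motif on a disc-shaped fruit background, so that a small CNN can separate
#' the labels and label-wise spatial aggregation is meaningful. Colours are RGB
#' in `[0, 1]`; sizes are fractions of the image side.
#'
#' @param image_size Image side length in pixels.
#' @return Named list of per-label motif parameter lists.
#' @export
default_motif_params <- function(image_size = 64) {
  list(
    n  = list(type = "none"),
    r  = list(type = "speckle", color = c(0.55, 0.38, 0.22),
              radius = c(0.10, 0.17), n_dots = 45, dot_radius = 0.014),
    mr = list(type = "blob", color = c(0.26, 0.14, 0.08),
              radius = c(0.07, 0.11)),
    sr = list(type = "blob", color = c(0.08, 0.04, 0.04),
              radius = c(0.15, 0.21)),
    c  = list(type = "crack", color = c(0.12, 0.07, 0.05),
              length = c(0.35, 0.55), width = 0.012),
    s  = list(type = "ridges", color = c(0.30, 0.16, 0.10),
              n_ridges = 4, spacing = 0.045, width = 0.010),
    p  = list(type = "patch", color = c(0.88, 0.76, 0.58),
              radius = c(0.09, 0.15)),
    bp = list(type = "punctures", color = c(0.10, 0.06, 0.05),
              n_holes = 4, hole_radius = 0.022, cluster_radius = 0.07)
  )
}

#' Build the default dataset specification
#'
#' Returns the dataset specification whose label-combination census matches
#' the benchmark multilabel jujube defect dataset: 18 combinations, 1930
#' samples in total (660 single-label, 1200 double-label, 70 triple-label).
#'
#' @param image_size Side length in pixels of the square images (default 64,
#'   a desk-scale size; use 299 with the `inception_v3` backbone).
#' @param seed Integer seed from which every per-sample rendering seed is
#'   derived.
#' @return An object of class `farnet_dataset_spec` with fields `labels`,
#'   `combos` (list of `(labels, count)` pairs), `image_size`, `motif_params`
#'   and `seed`.
#' @export
#' @examples
#' spec <- make_default_spec()
#' sum(vapply(spec$combos, function(co) co$count, integer(1)))  # 1930
make_default_spec <- function(image_size = 64, seed = 1) {
  spec <- list(labels = jujube_labels(), combos = default_combos(),
               image_size = as.integer(image_size),
               motif_params = default_motif_params(image_size),
               seed = as.integer(seed))
  class(spec) <- "farnet_dataset_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  stopifnot(length(spec$labels) >= 2, !anyDuplicated(spec$labels))
  for (co in spec$combos) {
    if (length(co$labels) == 0) {
      stop("every label combination must be nonempty", call. = FALSE)
    }
    unknown <- setdiff(co$labels, spec$labels)
    if (length(unknown)) {
      stop("unknown label(s) in combination: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (co$count <= 0) stop("combination counts must be positive",
                            call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.farnet_dataset_spec <- function(x, ...) {
  total <- sum(vapply(x$combos, function(co) co$count, numeric(1)))
  cat("Multilabel defect dataset spec:", length(x$combos), "combinations,",
      total, "samples,", x$image_size, "x", x$image_size, "px, seed",
      x$seed, "\n")
  invisible(x)
}

# ---- rendering ------------------------------------------------------------

# Disc-shaped fruit background with mild radial shading and hue jitter.
# Consumes the current RNG stream.
render_background <- function(size) {
  ax <- (seq_len(size) - 0.5) / size
  xg <- matrix(ax, size, size)
  yg <- matrix(ax, size, size, byrow = TRUE)
  r2 <- (xg - 0.5)^2 + (yg - 0.5)^2
  disc <- r2 < 0.42^2
  base <- c(0.55, 0.22, 0.15) + stats::runif(3, -0.04, 0.04)
  shade <- 1 - 0.6 * r2 / 0.42^2
  img <- array(0.06, c(size, size, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- (base[ch] * shade)[disc]
    img[, , ch] <- plane
  }
  list(img = img, disc = disc, xg = xg, yg = yg)
}

# Uniform point inside the fruit disc (rejection-free: polar sampling).
sample_in_disc <- function(margin = 0.05) {
  rad <- (0.42 - margin) * sqrt(stats::runif(1))
  ang <- stats::runif(1, 0, 2 * pi)
  c(0.5 + rad * cos(ang), 0.5 + rad * sin(ang))
}

paint_mask <- function(img, mask, color, alpha) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * color[ch]
    img[, , ch] <- plane
  }
  img
}

draw_motif <- function(img, bg, mp) {
  xg <- bg$xg; yg <- bg$yg
  # Contrast jitter: occasionally faint motifs keep per-label evidence
  # imperfect, so co-occurrence priors carry usable signal.
  alpha <- stats::runif(1, 0.55, 1.0)
  switch(mp$type,
    none = img,
    blob = {
      ctr <- sample_in_disc(0.08)
      rad <- stats::runif(1, mp$radius[1], mp$radius[2])
      mask <- ((xg - ctr[1])^2 + (yg - ctr[2])^2 < rad^2) & bg$disc
      paint_mask(img, mask, mp$color, alpha)
    },
    patch = {
      ctr <- sample_in_disc(0.08)
      rad <- stats::runif(1, mp$radius[1], mp$radius[2])
      ang <- atan2(yg - ctr[2], xg - ctr[1])
      wob <- 1 + 0.25 * sin(3 * ang + stats::runif(1, 0, 2 * pi))
      mask <- ((xg - ctr[1])^2 + (yg - ctr[2])^2 < (rad * wob)^2) & bg$disc
      paint_mask(img, mask, mp$color, alpha)
    },
    speckle = {
      ctr <- sample_in_disc(0.08)
      rad <- stats::runif(1, mp$radius[1], mp$radius[2])
      mask <- matrix(FALSE, nrow(xg), ncol(xg))
      for (k in seq_len(mp$n_dots)) {
        a <- stats::runif(1, 0, 2 * pi)
        d <- rad * sqrt(stats::runif(1))
        cx <- ctr[1] + d * cos(a); cy <- ctr[2] + d * sin(a)
        mask <- mask | ((xg - cx)^2 + (yg - cy)^2 < mp$dot_radius^2)
      }
      paint_mask(img, mask & bg$disc, mp$color, alpha)
    },
    crack = {
      start <- sample_in_disc(0.10)
      dir <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, mp$length[1], mp$length[2])
      curv <- stats::runif(1, -2, 2)
      t <- seq(0, 1, length.out = 80)
      px <- start[1] + t * len * cos(dir + curv * t)
      py <- start[2] + t * len * sin(dir + curv * t)
      mask <- matrix(FALSE, nrow(xg), ncol(xg))
      for (k in seq_along(t)) {
        mask <- mask | ((xg - px[k])^2 + (yg - py[k])^2 < mp$width^2)
      }
      paint_mask(img, mask & bg$disc, mp$color, alpha)
    },
    ridges = {
      ctr <- sample_in_disc(0.12)
      dir <- stats::runif(1, 0, 2 * pi)
      nx <- cos(dir); ny <- sin(dir)
      mask <- matrix(FALSE, nrow(xg), ncol(xg))
      for (k in seq_len(mp$n_ridges)) {
        off <- (k - (mp$n_ridges + 1) / 2) * mp$spacing
        d <- abs((xg - ctr[1] - off * nx) * nx + (yg - ctr[2] - off * ny) * ny)
        along <- abs(-(xg - ctr[1]) * ny + (yg - ctr[2]) * nx)
        mask <- mask | (d < mp$width & along < 0.16)
      }
      paint_mask(img, mask & bg$disc, mp$color, alpha)
    },
    punctures = {
      ctr <- sample_in_disc(0.10)
      mask <- matrix(FALSE, nrow(xg), ncol(xg))
      for (k in seq_len(mp$n_holes)) {
        a <- stats::runif(1, 0, 2 * pi)
        d <- mp$cluster_radius * sqrt(stats::runif(1))
        cx <- ctr[1] + d * cos(a); cy <- ctr[2] + d * sin(a)
        mask <- mask | ((xg - cx)^2 + (yg - cy)^2 < mp$hole_radius^2)
      }
      paint_mask(img, mask & bg$disc, mp$color, alpha)
    },
    stop("unknown motif type: ", mp$type)
  )
}

#' Render one synthetic defect sample
#'
#' Draws a disc-shaped fruit on a dark background and one visually distinct
#' motif per label in `combo` (dark blob for rot, thin line for cracking,
#' bright patch for peeling, ...). Rendering is a pure function of
#' `(combo, motif_params, seed)`; the caller's RNG stream is left untouched.
#'
#' @param combo Character vector of label codes present in the sample.
#' @param image_size Image side length in pixels.
#' @param motif_params Per-label motif parameters
#'   (default [default_motif_params()]).
#' @param seed Integer rendering seed.
#' @param labels Label vocabulary defining the order of the target vector.
#' @param id Sample identifier string.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @return An object of class `farnet_sample`: list with `pixels`
#'   (`image_size` x `image_size` x 3 array in `[0, 1]`), `y` (named
#'   multi-hot integer vector) and `id`.
#' @export
#' @examples
#' s <- render_sample(c("r", "p"), seed = 7)
#' sum(s$y)  # 2
render_sample <- function(combo, image_size = 64, motif_params = NULL,
                          seed = 1, labels = jujube_labels(),
                          id = paste(combo, collapse = "+"),
                          noise_sd = 0.04) {
  if (length(combo) == 0) stop("combo must be nonempty", call. = FALSE)
  unknown <- setdiff(combo, labels)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  motif_params <- motif_params %||% default_motif_params(image_size)
  img <- with_seed(seed, {
    bg <- render_background(image_size)
    out <- bg$img
    for (lab in labels[labels %in% combo]) {
      out <- draw_motif(out, bg, motif_params[[lab]])
    }
    if (noise_sd > 0) {
      out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
    }
    out
  })
  img[img < 0] <- 0; img[img > 1] <- 1
  y <- as.integer(labels %in% combo)
  names(y) <- labels
  structure(list(pixels = img, y = y, id = id), class = "farnet_sample")
}

# ---- dataset generation ---------------------------------------------------

combo_key <- function(index) {
  labels <- attr(index, "labels")
  apply(index[, labels, drop = FALSE], 1, paste, collapse = "")
}

#' Generate a synthetic multilabel defect dataset
#'
#' Renders one image per count unit of every label combination in the spec,
#' following the census literally, and returns a dataset index whose multi-hot
#' rows match the rendered images exactly. With `dir = NULL` images are kept
#' in memory (an H x W x 3 x N array); otherwise PNGs and an annotation CSV
#' (`id,n,r,mr,sr,c,s,p,bp`) are written under `dir`.
#'
#' @param spec A `farnet_dataset_spec`, e.g. [make_default_spec()].
#' @param dir Output directory, or `NULL` to keep images in memory.
#' @param force Overwrite a non-empty `dir`.
#' @param verbose Print progress.
#' @return List with `index` (class `farnet_index`: data.frame of `id`, one
#'   0/1 column per label, `split`) and `images` (4-D array, or `NULL` when
#'   written to disk).
#' @export
generate_dataset <- function(spec, dir = NULL, force = FALSE,
                             verbose = FALSE) {
  validate_spec(spec)
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
      stop("output directory ", dir, " is not empty; use force = TRUE",
           call. = FALSE)
    }
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    ok <- file.access(dir, 2) == 0
    if (!ok) stop("output directory ", dir, " is not writable", call. = FALSE)
  }
  total <- sum(vapply(spec$combos, function(co) co$count, numeric(1)))
  size <- spec$image_size
  if (is.null(dir) && total * size^2 * 3 * 8 > 2e9) {
    stop("in-memory dataset would exceed 2 GB; pass dir = to write PNGs ",
         "instead", call. = FALSE)
  }
  ids <- character(total)
  ymat <- matrix(0L, total, length(spec$labels),
                 dimnames = list(NULL, spec$labels))
  images <- if (is.null(dir)) array(0, c(size, size, 3, total)) else NULL
  i <- 0L
  for (co in spec$combos) {
    tag <- paste(co$labels, collapse = "-")
    for (k in seq_len(co$count)) {
      i <- i + 1L
      id <- sprintf("%s_%04d", tag, k)
      smp <- render_sample(co$labels, image_size = size,
                           motif_params = spec$motif_params,
                           seed = derive_seed(spec$seed, i),
                           labels = spec$labels, id = id)
      ids[i] <- id
      ymat[i, ] <- smp$y
      if (is.null(dir)) {
        images[, , , i] <- smp$pixels
      } else {
        png::writePNG(smp$pixels, file.path(dir, "images",
                                            paste0(id, ".png")))
      }
    }
    if (verbose) message("rendered ", tag, " x", co$count)
  }
  index <- data.frame(id = ids, ymat, split = NA_character_,
                      stringsAsFactors = FALSE, check.names = FALSE)
  attr(index, "labels") <- spec$labels
  class(index) <- c("farnet_index", "data.frame")
  if (!is.null(dir)) {
    write_annotations(index, file.path(dir, "annotations.csv"))
  }
  list(index = index, images = images)
}

#' Write / read a dataset annotation table
#'
#' CSV dialect: header `id,<label columns...>[,split]`, one row per image,
#' 0/1 cells for labels.
#'
#' @param index A `farnet_index`.
#' @param file Path to the CSV file.
#' @return `write_annotations` returns the path invisibly;
#'   `read_annotations` returns a `farnet_index`.
#' @export
write_annotations <- function(index, file) {
  utils::write.csv(as.data.frame(index), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- setdiff(names(df), c("id", "split"))
  if (!"split" %in% names(df)) df$split <- NA_character_
  attr(df, "labels") <- labels
  class(df) <- c("farnet_index", "data.frame")
  df
}

#' Split a dataset index into train / validation / test sets
#'
#' Stratified by label combination: within every combination the records are
#' shuffled (deterministically, from `seed`) and allocated to the parts of
#' `ratio` by exact proportion with largest-remainder rounding, so per-
#' combination split sizes are within one of the exact ratio. The default
#' 3:1:1 split of the census dataset is exact: 1158 / 386 / 386.
#'
#' @param index A `farnet_index`.
#' @param ratio Positive numeric vector, one entry per split part.
#' @param seed Integer seed.
#' @param names Split tag names, defaulting to train/val/test.
#' @return The index with its `split` column filled.
#' @export
split_dataset <- function(index, ratio = c(3, 1, 1), seed = 1,
                          names = c("train", "val", "test")) {
  stopifnot(all(ratio > 0), length(ratio) == length(names))
  key <- combo_key(index)
  split <- rep(NA_character_, nrow(index))
  groups <- split(seq_len(nrow(index)), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  with_seed(seed, {
    for (rows in groups) {
      n <- length(rows)
      if (n < length(ratio)) {
        warning("combination with ", n,
                " record(s) has fewer records than split parts; ",
                "assigning all to ", names[1], call. = FALSE)
        split[rows] <- names[1]
        next
      }
      exact <- n * ratio / sum(ratio)
      sizes <- floor(exact)
      rem <- n - sum(sizes)
      if (rem > 0) {
        extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1
      }
      rows <- sample(rows)
      split[rows] <- rep(names, times = sizes)
    }
  })
  index$split <- split
  index
}

#' Summary statistics of a dataset index
#'
#' @param index A nonempty `farnet_index`.
#' @return An object of class `farnet_stats`: list with `total`, `cardinality`
#'   (named counts of records by number of set labels), `per_label_pct`
#'   (percentage of records carrying each label, one decimal place) and
#'   `multilabel_pct` (percentage of records with two or more labels).
#' @export
#' @examples
#' ds <- generate_dataset(make_default_spec())
#' dataset_stats(ds$index)$multilabel_pct  # 65.8
dataset_stats <- function(index) {
  if (nrow(index) == 0) stop("dataset index is empty", call. = FALSE)
  labels <- attr(index, "labels")
  ymat <- as.matrix(index[, labels, drop = FALSE])
  card <- rowSums(ymat)
  cardinality <- table(factor(card, levels = sort(unique(card))))
  per_label <- round(100 * colSums(ymat) / nrow(index), 1)
  stats <- list(total = nrow(index),
                cardinality = stats::setNames(as.integer(cardinality),
                                              names(cardinality)),
                per_label_pct = per_label,
                multilabel_pct = round(100 * mean(card >= 2), 1))
  class(stats) <- "farnet_stats"
  stats
}

#' @export
print.farnet_stats <- function(x, ...) {
  cat("Records:", x$total, "\n")
  cat("By cardinality:",
      paste(sprintf("%s-label: %d", names(x$cardinality), x$cardinality),
            collapse = ", "), "\n")
  cat("Multilabel fraction:", x$multilabel_pct, "%\n")
  cat("Per-label frequency (%):\n")
  print(x$per_label_pct)
  invisible(x)
}

#' Read a generated dataset back from disk
#'
#' @param dir Directory previously written by [generate_dataset()].
#' @return List with `index` and `images` (4-D array).
#' @export
read_dataset <- function(dir) {
  ann <- file.path(dir, "annotations.csv")
  if (!file.exists(ann)) {
    stop("no dataset found at ", dir, " (missing annotations.csv)",
         call. = FALSE)
  }
  index <- read_annotations(ann)
  first <- png::readPNG(file.path(dir, "images",
                                  paste0(index$id[1], ".png")))
  images <- array(0, c(dim(first), nrow(index)))
  images[, , , 1] <- first
  for (i in seq_len(nrow(index))[-1]) {
    images[, , , i] <- png::readPNG(file.path(dir, "images",
                                              paste0(index$id[i], ".png")))
  }
  list(index = index, images = images)
}

# Label pairs that ever / never co-occur under a dataset spec.
# Returns a list of two matrices of pair name pairs (rows: m, l with m < l).
cooccurrence_pairs <- function(spec) {
  labels <- spec$labels
  C <- length(labels)
  seen <- matrix(FALSE, C, C, dimnames = list(labels, labels))
  for (co in spec$combos) {
    if (length(co$labels) >= 2) {
      pr <- utils::combn(match(co$labels, labels), 2)
      for (k in seq_len(ncol(pr))) {
        seen[pr[1, k], pr[2, k]] <- TRUE
        seen[pr[2, k], pr[1, k]] <- TRUE
      }
    }
  }
  idx <- which(upper.tri(seen), arr.ind = TRUE)
  co <- idx[seen[idx], , drop = FALSE]
  non <- idx[!seen[idx], , drop = FALSE]
  list(cooccurring = co, never = non, labels = labels)
}
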