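#' Microbial freshness grading table
#'
#' The five pork freshness grades with their representative microbial
#' colony concentrations (in units of 10^3 CFU/g) and chilled storage
#' times. The fresh limit — the total colony count that fresh meat must not
#' exceed — is 10^6 CFU/g and is carried as the `fresh_limit` attribute.
#'
#' @return a `grade_table` data frame with columns `grade`,
#'   `concentration_kcfu` (10^3 CFU/g) and `storage_h` (hours).
#' @export
freshness_grade_table <- function() {
  tab <- data.frame(
    grade = c("First-grade fresh pork", "Second-grade fresh pork",
              "Third-grade fresh pork", "First-grade spoiled pork",
              "Second-grade spoiled pork"),
    concentration_kcfu = c(4.168, 13.182, 301.995, 1778.279, 5370.317),
    storage_h = c(0, 24, 48, 72, 96),
    stringsAsFactors = FALSE
  )
  structure(tab, fresh_limit = 1e6, class = c("grade_table", "data.frame"))
}

validate_grade_table <- function(table) {
  if (nrow(table) != 5L) {
    stop("grade table must have exactly 5 grades", call. = FALSE)
  }
  conc <- table$concentration_kcfu
  if (any(diff(conc) <= 0) || any(diff(table$storage_h) <= 0)) {
    stop("grade table concentrations/storage times must be strictly increasing",
         call. = FALSE)
  }
  fl <- attr(table, "fresh_limit")
  if (is.null(fl) || fl <= 0) {
    stop("grade table needs a positive fresh_limit attribute", call. = FALSE)
  }
  invisible(table)
}

# bin edges in CFU/g: geometric means of consecutive tabulated
# concentrations, with the fresh/spoiled edge forced to the fresh limit
grade_bin_edges <- function(table) {
  conc <- table$concentration_kcfu * 1e3
  edges <- sqrt(conc[-length(conc)] * conc[-1])
  n_fresh <- sum(grepl("fresh", table$grade, ignore.case = TRUE))
  edges[n_fresh] <- attr(table, "fresh_limit")
  edges
}

#' Grade a sample from its microbial colony count
#'
#' Maps a colony concentration (CFU/g) to a freshness grade. The tabulated
#' concentrations are representative values, not interval edges, so grades
#' are assigned by half-open bins whose upper edges sit at the geometric
#' means of consecutive tabulated concentrations — except the fresh/spoiled
#' boundary, which is pinned to the fresh limit (counts up to and including
#' 10^6 CFU/g are still fresh: the limit is "must not exceed").
#'
#' @param count microbial colony concentration(s) in CFU/g; must be
#'   positive.
#' @param table a [freshness_grade_table()].
#' @return character vector of grade names.
#' @examples
#' grade_from_colony_count(4.168e3)
#' grade_from_colony_count(1.778279e6)
#' @export
grade_from_colony_count <- function(count, table = freshness_grade_table()) {
  validate_grade_table(table)
  if (any(!is.finite(count)) || any(count <= 0)) {
    stop("colony count must be positive and finite", call. = FALSE)
  }
  edges <- grade_bin_edges(table)
  idx <- findInterval(count, edges, left.open = TRUE) + 1L
  table$grade[idx]
}

#' Synthetic image generator configuration
#'
#' The generator emulates the photographic structure of graded meat
#' surfaces: class identity is carried by a hue that drifts with spoilage
#' grade (bright red toward dark brownish red), surface luster is a
#' class-independent multiplicative brightness factor (log-normal with
#' standard deviation `luster_jitter_sd` on the log scale), and local
#' texture is smooth multiplicative noise with correlation length
#' `texture_grain` pixels. Class identity therefore lives in the
#' *direction* of the pixel/feature vector while luster perturbs its
#' *magnitude* — the premise motivating the cosine-similarity classifier.
#'
#' @param n_classes number of freshness grades (>= 2).
#' @param images_per_class images generated per class.
#' @param image_size square image side in pixels; must be divisible by 32
#'   so the backbone's stage-4 maps divide into region grids.
#' @param hue_start,hue_end class hue endpoints in degrees; class c of k
#'   gets hue `hue_start + (hue_end - hue_start) * c / (k - 1)`.
#' @param saturation,value base HSV saturation and brightness.
#' @param luster_jitter_sd standard deviation of the per-image log-normal
#'   brightness factor (0 disables).
#' @param texture_grain correlation length of the texture noise in pixels
#'   (0 disables).
#' @param texture_amp relative amplitude of the texture noise.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 5, images_per_class = 20,
                         image_size = 224, hue_start = 10, hue_end = 50,
                         saturation = 0.8, value = 0.7,
                         luster_jitter_sd = 0.15, texture_grain = 4,
                         texture_amp = 0.08, seed = 1) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (image_size %% 32 != 0) {
    stop("image_size must be divisible by 32", call. = FALSE)
  }
  if (luster_jitter_sd < 0) {
    stop("luster_jitter_sd must be >= 0", call. = FALSE)
  }
  structure(list(n_classes = n_classes,
                 images_per_class = as.integer(images_per_class),
                 image_size = as.integer(image_size),
                 hue_start = hue_start, hue_end = hue_end,
                 saturation = saturation, value = value,
                 luster_jitter_sd = luster_jitter_sd,
                 texture_grain = texture_grain, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# vectorized HSV -> RGB; h in degrees (any real, wrapped), s/v in [0,1].
# Returns a list of three arrays shaped like v.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# smooth unit-variance-ish noise field: coarse gaussian grid scaled up
# bilinearly to size x size, correlation length ~ grain pixels
smooth_noise_field <- function(size, grain) {
  gs <- max(2L, as.integer(ceiling(size / grain)) + 1L)
  coarse <- matrix(stats::rnorm(gs * gs), gs, gs)
  # bilinear interpolation onto the pixel grid
  pos <- (seq_len(size) - 0.5) / size * (gs - 1) + 1
  i0 <- pmin(floor(pos), gs - 1)
  fr <- pos - i0
  row0 <- coarse[i0, , drop = FALSE]
  row1 <- coarse[i0 + 1, , drop = FALSE]
  rows <- row0 * (1 - fr) + row1 * fr
  col0 <- rows[, i0, drop = FALSE]
  col1 <- rows[, i0 + 1, drop = FALSE]
  col0 * (1 - rep(fr, each = size)) + col1 * rep(fr, each = size)
}

#' Generate a batch of synthetic freshness-graded images
#'
#' Deterministic for a fixed config (the seed is part of the config): the
#' same call yields bit-identical batches. Labels are balanced (exactly
#' `images_per_class` per class) and ordered by class.
#'
#' @param config a [synth_config()].
#' @return an `image_batch`: list with `pixels` (array
#'   `(n, 3, size, size)` of RGB values in `[0,1]`) and 0-based integer
#'   `labels`.
#' @export
generate_images <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$n_classes
  m <- config$images_per_class
  sz <- config$image_size
  pixels <- array(0, c(k * m, 3L, sz, sz))
  labels <- rep(0:(k - 1L), each = m)
  hues <- config$hue_start +
    (config$hue_end - config$hue_start) * (0:(k - 1L)) / (k - 1L)
  withr::with_seed(config$seed, {
    idx <- 0L
    for (c in seq_len(k)) {
      for (j in seq_len(m)) {
        idx <- idx + 1L
        vfield <- matrix(config$value, sz, sz)
        if (config$texture_grain > 0 && config$texture_amp > 0) {
          vfield <- vfield *
            (1 + config$texture_amp * smooth_noise_field(sz, config$texture_grain))
        }
        if (config$luster_jitter_sd > 0) {
          vfield <- vfield * exp(stats::rnorm(1L, sd = config$luster_jitter_sd))
        }
        vfield <- pmin(pmax(vfield, 0), 1)
        rgb <- hsv_to_rgb(hues[c], config$saturation, vfield)
        pixels[idx, 1L, , ] <- rgb$r
        pixels[idx, 2L, , ] <- rgb$g
        pixels[idx, 3L, , ] <- rgb$b
      }
    }
  })
  structure(list(pixels = pixels, labels = labels, config = config),
            class = "image_batch")
}

#' Write / read a generated image dataset as PNG files
#'
#' Directory-per-class layout `root/class_<i>/img_<j>.png` with a sidecar
#' `labels.csv` (filename, class, grade_name). Grade names come from the
#' grading table in class order.
#'
#' @param batch an `image_batch` from [generate_images()].
#' @param dir output directory root.
#' @param table a [freshness_grade_table()] used for the grade-name column.
#' @return `write_image_dataset()` returns the labels data frame
#'   invisibly; `read_image_dataset()` returns an `image_batch`.
#' @export
write_image_dataset <- function(batch, dir,
                                table = freshness_grade_table()) {
  stopifnot(inherits(batch, "image_batch"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grades <- table$grade
  rows <- vector("list", length(batch$labels))
  counter <- integer(max(batch$labels) + 1L)
  for (i in seq_along(batch$labels)) {
    cls <- batch$labels[i]
    cdir <- file.path(dir, sprintf("class_%d", cls))
    dir.create(cdir, showWarnings = FALSE)
    counter[cls + 1L] <- counter[cls + 1L] + 1L
    fn <- file.path(cdir, sprintf("img_%04d.png", counter[cls + 1L]))
    img <- aperm(batch$pixels[i, , , ], c(2L, 3L, 1L))
    png::writePNG(img, fn)
    rows[[i]] <- data.frame(
      filename = fn, class = cls,
      grade_name = if (cls + 1L <= length(grades)) grades[cls + 1L] else
        sprintf("class_%d", cls),
      stringsAsFactors = FALSE)
  }
  labels_df <- do.call(rbind, rows)
  utils::write.csv(labels_df, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(labels_df)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    stop("no labels.csv under ", dir, call. = FALSE)
  }
  labels_df <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  first <- png::readPNG(labels_df$filename[1])
  sz <- dim(first)[1:2]
  n <- nrow(labels_df)
  pixels <- array(0, c(n, 3L, sz[1], sz[2]))
  for (i in seq_len(n)) {
    img <- png::readPNG(labels_df$filename[i])
    pixels[i, , , ] <- aperm(img[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
  }
  structure(list(pixels = pixels, labels = labels_df$class),
            class = "image_batch")
}

#' Generate a feature-space episode with directional class structure
#'
#' Builds k unit direction vectors with pairwise angular separation
#' `angle_sep` and samples each item as
#' `direction * exp(sd * z) + noise_sd * N(0, I)`: class identity lives
#' entirely in the direction, while the log-normal magnitude factor
#' emulates class-independent luster variation. With `noise_sd = 0` all
#' samples of a class are exactly collinear with its direction, so the
#' cosine classifier is perfect for any magnitude jitter.
#'
#' Directions are constructed as
#' `cos(a) * u + sin(a) * e_i` for orthonormal `e_i` and a common unit
#' vector `u` orthogonal to all of them, giving pairwise angle
#' `acos(cos(a)^2)`; separations up to 90 degrees are representable
#' (requires `dim >= k + 1` below 90 degrees, `dim >= k` at exactly 90).
#' A random seeded rotation is applied afterwards.
#'
#' @param k ways (>= 2).
#' @param n support shots per class.
#' @param q query items per class.
#' @param dim feature dimensionality.
#' @param angle_sep pairwise angular separation of the class directions,
#'   radians, in `(0, pi/2]`.
#' @param mag_jitter_sd standard deviation (log scale) of the magnitude
#'   factor.
#' @param noise_sd isotropic feature noise standard deviation.
#' @param seed integer seed.
#' @return an `episode` (see [sample_episode()]) whose `x` fields are
#'   feature matrices; also carries the `directions` matrix.
#' @export
generate_feature_episode <- function(k, n, q, dim, angle_sep,
                                     mag_jitter_sd = 0, noise_sd = 0,
                                     seed = 1) {
  k <- as.integer(k)
  dim <- as.integer(dim)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (dim < k) stop("dim must be >= k", call. = FALSE)
  if (!(angle_sep > 0)) stop("angle_sep must be positive", call. = FALSE)
  if (angle_sep > pi / 2 + 1e-12) {
    stop(sprintf(
      "angle_sep=%.3f rad infeasible for (k=%d, dim=%d): this construction covers (0, pi/2]",
      angle_sep, k, dim), call. = FALSE)
  }
  exact_orth <- abs(angle_sep - pi / 2) < 1e-12
  if (!exact_orth && dim < k + 1L) {
    stop(sprintf(
      "angle_sep below pi/2 needs dim >= k + 1 (got k=%d, dim=%d)", k, dim),
      call. = FALSE)
  }
  withr::with_seed(seed, {
    alpha <- acos(sqrt(cos(angle_sep)))
    D <- matrix(0, k, dim)
    for (i in seq_len(k)) D[i, i] <- sin(alpha)
    if (!exact_orth) D[, k + 1L] <- cos(alpha)
    # random rotation from the QR decomposition of a gaussian matrix
    Qr <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim)))
    D <- D %*% Qr
    D <- unit_rows(D)

    draw <- function(per_class) {
      X <- matrix(0, k * per_class, dim)
      y <- integer(k * per_class)
      row <- 0L
      for (c in seq_len(k)) {
        for (j in seq_len(per_class)) {
          row <- row + 1L
          mag <- exp(stats::rnorm(1L, sd = mag_jitter_sd))
          x <- D[c, ] * mag
          if (noise_sd > 0) x <- x + stats::rnorm(dim, sd = noise_sd)
          X[row, ] <- x
          y[row] <- c - 1L
        }
      }
      list(x = X, labels = y, index = seq_len(k * per_class))
    }
    support <- draw(n)
    query <- draw(q)
  })
  structure(list(support = support, query = query,
                 k = k, n = as.integer(n), q = as.integer(q),
                 classes = 0:(k - 1L), directions = D),
            class = "episode")
}

#' Save / load a feature episode
#'
#' `episode_save()` writes `<prefix>.json` (a manifest with k/n/q,
#' dimensionality, labels, storage layout) and `<prefix>.bin` (the support
#' then query feature rows as little-endian float64, row-major).
#'
#' @param episode an episode with feature-matrix `x` fields.
#' @param prefix path prefix for the two files.
#' @return `episode_load()` returns the episode.
#' @export
episode_save <- function(episode, prefix) {
  Fs <- as.matrix(episode$support$x)
  Fq <- as.matrix(episode$query$x)
  manifest <- list(
    k = episode$k, n = episode$n, q = episode$q,
    dim = ncol(Fs),
    support_rows = nrow(Fs), query_rows = nrow(Fq),
    support_labels = episode$support$labels,
    query_labels = episode$query$labels,
    dtype = "float64", byte_order = "little", layout = "row-major"
  )
  jsonlite::write_json(manifest, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rbind(Fs, Fq))), con, size = 8L, endian = "little")
  invisible(prefix)
}

#' @rdname episode_save
#' @export
episode_load <- function(prefix) {
  manifest <- jsonlite::read_json(paste0(prefix, ".json"),
                                  simplifyVector = TRUE)
  n_all <- manifest$support_rows + manifest$query_rows
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n_all * manifest$dim, size = 8L,
               endian = "little")
  X <- matrix(v, n_all, manifest$dim, byrow = TRUE)
  structure(list(
    support = list(x = X[seq_len(manifest$support_rows), , drop = FALSE],
                   labels = manifest$support_labels,
                   index = seq_len(manifest$support_rows)),
    query = list(x = X[manifest$support_rows + seq_len(manifest$query_rows), ,
                       drop = FALSE],
                 labels = manifest$query_labels,
                 index = seq_len(manifest$query_rows)),
    k = manifest$k, n = manifest$n, q = manifest$q,
    classes = 0:(manifest$k - 1L)),
    class = "episode")
}
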