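#' Construct an image record
#'
#' An image record is the atomic unit of a cohort: one RGB snapshot belonging
#' to one patient. Pixels are stored as an `H x W x 3` integer array with
#' channel values in `[0, 255]`.
#'
#' @param patient_id Opaque patient identifier (scalar character).
#' @param image_id Identifier unique within the patient (scalar character).
#' @param pixels `H x W x 3` numeric array, integer-valued in `[0, 255]`.
#' @param source_path Optional path the image was loaded from.
#' @return An object of class `image_record`.
#' @export
image_record <- function(patient_id, image_id, pixels, source_path = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.character(image_id), length(image_id) == 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("image must have H >= 1 and W >= 1")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(patient_id = patient_id, image_id = image_id,
         pixels = pixels, source_path = source_path),
    class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record %s/%s %dx%dx3>\n",
              x$patient_id, x$image_id, d[1], d[2]))
  invisible(x)
}

LABEL_LEVELS <- c("negative", "positive", "unknown")

#' Parse cohort labels to the internal ternary domain
#'
#' Accepted spellings (case-insensitive): `"IBD"`, `"positive"`, `"1"` map to
#' positive; `"control"`, `"negative"`, `"healthy"`, `"0"` map to negative;
#' `"unknown"`, `"NA"` and `NA` map to unknown. Anything else is an error.
#'
#' @param x Character vector of label strings.
#' @return Character vector over `{"positive","negative","unknown"}`.
#' @export
parse_label <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lx))
  out[lx %in% c("ibd", "positive", "pos", "1")] <- "positive"
  out[lx %in% c("control", "negative", "neg", "healthy", "0")] <- "negative"
  out[is.na(lx) | lx %in% c("unknown", "na", "")] <- "unknown"
  if (anyNA(out))
    stop("unknown label string(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Serialize an internal label for manifests
#' @param x Internal label(s) in `{"positive","negative","unknown"}`.
#' @return `"IBD"` / `"control"` / `"unknown"`.
#' @export
format_label <- function(x) {
  c(positive = "IBD", negative = "control", unknown = "unknown")[x]
}

#' Construct a patient case
#'
#' A patient case bundles a patient's ordered image sequence (length may be
#' zero and varies across patients) with the diagnostic label. It is the unit
#' on which per-patient inference operates.
#'
#' @param patient_id Patient identifier.
#' @param label One of `"positive"` (IBD), `"negative"` (control), `"unknown"`.
#' @param images List of [image_record()] objects, all with this `patient_id`,
#'   with `image_id` unique within the case.
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient_id, label = "unknown", images = list()) {
  label <- match.arg(label, LABEL_LEVELS)
  ids <- vapply(images, function(im) im$image_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate image_id within patient ", patient_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pids <- vapply(images, function(im) im$patient_id, character(1))
  if (length(pids) && any(pids != patient_id))
    stop("image records carry a different patient_id than the case")
  structure(list(patient_id = patient_id, label = label, images = images),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case %s label=%s images=%d>\n",
              x$patient_id, x$label, length(x$images)))
  invisible(x)
}

#' Construct a cohort
#'
#' @param cases List of [patient_case()] objects with unique patient ids.
#' @return An object of class `cohort`; cases are kept in input order and
#'   named by patient id.
#' @export
cohort <- function(cases) {
  ids <- vapply(cases, function(cs) cs$patient_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient_id across cases: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(cases) <- ids
  structure(list(cases = cases), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_img <- sum(vapply(x$cases, function(cs) length(cs$images), integer(1)))
  lab <- table(factor(cohort_labels(x), levels = LABEL_LEVELS))
  cat(sprintf("<cohort: %d patients, %d images (pos %d / neg %d / unk %d)>\n",
              length(x$cases), n_img, lab[["positive"]], lab[["negative"]],
              lab[["unknown"]]))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$cases)

#' Patient ids of a cohort
#' @param x A [cohort()].
#' @return Character vector of patient ids.
#' @export
cohort_ids <- function(x) {
  vapply(x$cases, function(cs) cs$patient_id, character(1), USE.NAMES = FALSE)
}

#' Named vector of patient labels
#' @param x A [cohort()].
#' @return Character vector named by patient id.
#' @export
cohort_labels <- function(x) {
  out <- vapply(x$cases, function(cs) cs$label, character(1))
  names(out) <- cohort_ids(x)
  out
}

#' Load a cohort from a manifest file
#'
#' The manifest is either a CSV with header columns
#' `patient_id,label,image_path` (one row per image; a patient's images follow
#' manifest order) or a JSON array of case objects
#' `{patient_id, label, image_paths}`. Images are 8-bit RGB PNG files; paths
#' are resolved against `image_root`. Labels are parsed with [parse_label()].
#'
#' @param path Manifest file (`.csv` or `.json`).
#' @param image_root Directory against which relative image paths resolve;
#'   defaults to the manifest's directory.
#' @param load_pixels If `FALSE`, image records carry a 1x1x3 placeholder and
#'   only `source_path`; useful for split bookkeeping without touching pixels.
#' @return A [cohort()].
#' @export
load_manifest <- function(path, image_root = dirname(path),
                          load_pixels = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- do.call(rbind, lapply(raw, function(cs) {
      data.frame(patient_id = as.character(cs$patient_id),
                 label = as.character(cs$label),
                 image_path = as.character(unlist(cs$image_paths)),
                 stringsAsFactors = FALSE)
    }))
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("patient_id", "label", "image_path")
    if (!all(need %in% names(rows)))
      stop("manifest must have columns ", paste(need, collapse = ","))
  }
  rows$label <- parse_label(rows$label)
  cases <- lapply(split(seq_len(nrow(rows)), rows$patient_id), function(idx) {
    idx <- sort(idx)                       # preserve manifest order
    pid <- rows$patient_id[idx[1]]
    labs <- unique(rows$label[idx])
    if (length(labs) > 1L)
      stop("conflicting labels for patient ", pid, ": ",
           paste(labs, collapse = " vs "))
    imgs <- lapply(idx, function(i) {
      p <- rows$image_path[i]
      full <- if (startsWith(p, "/")) p else file.path(image_root, p)
      px <- if (load_pixels) read_image(full) else
        array(0L, dim = c(1L, 1L, 3L))
      image_record(pid, image_id = basename(p), pixels = px,
                   source_path = full)
    })
    patient_case(pid, labs, imgs)
  })
  # restore first-appearance order of patients
  first <- vapply(split(seq_len(nrow(rows)), rows$patient_id), min, integer(1))
  cohort(cases[order(first)])
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if missing). Images are written under
#'   `dir/images/<patient_id>/<image_id>.png`; the manifest at
#'   `dir/manifest.csv` uses paths relative to `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cs in x$cases) {
    pdir <- file.path(dir, "images", cs$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (im in cs$images) {
      fn <- paste0(sub("\\.png$", "", im$image_id), ".png")
      write_image(im$pixels, file.path(pdir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = cs$patient_id, label = format_label(cs$label),
        image_path = file.path("images", cs$patient_id, fn),
        stringsAsFactors = FALSE)
    }
  }
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE, quote = FALSE)
  invisible(man)
}

#' Patient-level train/test split
#'
#' Splits a cohort at the patient level so that every image of a patient lands
#' on exactly one side — the guard against information leakage from correlated
#' images of the same patient. The split is uniform over patients; optional
#' stratification by label keeps the class ratio on both sides.
#'
#' @param x A [cohort()].
#' @param test_fraction Proportion of patients assigned to the test side,
#'   in (0, 1); the study design uses 0.2.
#' @param seed Integer seed; the split is deterministic given
#'   (cohort, fraction, seed).
#' @param stratify_by_label If `TRUE`, split each label stratum separately.
#' @return An object of class `split_spec` with fields `seed`,
#'   `test_fraction`, `train_ids`, `test_ids`, `fold_of` (`NULL` until
#'   [assign_folds()] is applied).
#' @export
split_patients <- function(x, test_fraction = 0.2, seed = 1L,
                           stratify_by_label = FALSE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- cohort_ids(x)
  if (length(ids) < 2L) stop("cohort must contain at least 2 patients")
  pick_test <- function(pool, frac) {
    n_test <- max(1L, min(length(pool) - 1L, round(frac * length(pool))))
    sample(pool, n_test)
  }
  test_ids <- withr::with_seed(seed, {
    if (stratify_by_label) {
      labs <- cohort_labels(x)
      unlist(lapply(split(ids, labs[ids]), pick_test, frac = test_fraction),
             use.names = FALSE)
    } else {
      pick_test(ids, test_fraction)
    }
  })
  structure(
    list(seed = as.integer(seed), test_fraction = test_fraction,
         train_ids = setdiff(ids, test_ids), test_ids = test_ids,
         fold_of = NULL),
    class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec seed=%d train=%d test=%d folds=%s>\n",
              x$seed, length(x$train_ids), length(x$test_ids),
              if (is.null(x$fold_of)) "none" else
                length(unique(x$fold_of))))
  invisible(x)
}

#' Assign cross-validation folds at the patient level
#'
#' Partitions training patients into `n_folds` folds whose sizes differ by at
#' most one; fold indices run over `0 .. n_folds - 1`.
#'
#' @param train_ids Character vector of training patient ids.
#' @param n_folds Number of folds (>= 2); the study recipe uses 5.
#' @param seed Integer seed for the shuffle.
#' @return Named integer vector mapping patient id to fold index.
#' @export
assign_folds <- function(train_ids, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  if (n_folds > length(train_ids))
    stop("n_folds (", n_folds, ") exceeds number of training patients (",
         length(train_ids), ")")
  shuffled <- withr::with_seed(seed, sample(train_ids))
  fold <- rep_len(seq_len(n_folds) - 1L, length(shuffled))
  out <- integer(length(train_ids))
  names(out) <- train_ids
  out[shuffled] <- fold
  out
}

#' Serialize / deserialize a split specification as JSON
#'
#' @param spec A `split_spec`.
#' @param path Output (input) file path.
#' @return `write_split` returns `path` invisibly; `read_split` a
#'   `split_spec`.
#' @export
write_split <- function(spec, path) {
  jsonlite::write_json(
    list(seed = spec$seed, test_fraction = spec$test_fraction,
         train_ids = spec$train_ids, test_ids = spec$test_ids,
         fold_of = as.list(spec$fold_of)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fold_of <- NULL
  if (length(raw$fold_of)) {
    fold_of <- as.integer(unlist(raw$fold_of))
    names(fold_of) <- names(raw$fold_of)
  }
  structure(
    list(seed = as.integer(raw$seed), test_fraction = raw$test_fraction,
         train_ids = as.character(raw$train_ids),
         test_ids = as.character(raw$test_ids), fold_of = fold_of),
    class = "split_spec")
}

#' Subset a cohort by patient ids
#' @param x A [cohort()].
#' @param ids Patient ids to keep (order follows `ids`).
#' @return A [cohort()].
#' @export
subset_cohort <- function(x, ids) {
  missing <- setdiff(ids, names(x$cases))
  if (length(missing))
    stop("unknown patient id(s): ", paste(missing, collapse = ", "))
  cohort(x$cases[ids])
}
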