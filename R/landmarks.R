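#' Landmark names required for the craniofacial analysis
#'
#' Soft-tissue (Ex, C, Al, Sn), bone (Or, Po, N, S, Ba) and dental (U1, U6)
#' landmarks, with `_L`/`_R` suffixes for sided points. U1 is stored as a
#' single midpoint between the maxillary central incisor tips. Ba (basion)
#' is carried for completeness but enters no measurement.
#'
#' @export
REQUIRED_LANDMARKS <- c(
  "Ex_L", "Ex_R", "C_L", "C_R", "Al_L", "Al_R", "Sn",
  "Or_L", "Or_R", "Po_L", "Po_R", "N", "S", "Ba",
  "U1", "U6_L", "U6_R"
)

#' Named set of 3D anatomical landmarks
#'
#' @param points a named list of length-3 numeric vectors, or a numeric
#'   matrix with 3 columns and landmark names as row names. Coordinates in
#'   mm, scanner space.
#' @param require_all if `TRUE` (default) all landmarks in
#'   [REQUIRED_LANDMARKS] must be present.
#' @return object of class `landmark_set`: a k x 3 matrix with named rows.
#' @export
landmark_set <- function(points, require_all = TRUE) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("landmarks must have 3 coordinates")
  if (is.null(rownames(points))) stop("landmarks must be named")
  if (require_all) {
    missing <- setdiff(REQUIRED_LANDMARKS, rownames(points))
    if (length(missing) > 0L) {
      stop("incomplete landmark set: missing ", paste(missing, collapse = ", "))
    }
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop("incomplete landmark set: non-finite coordinates")
  }
  colnames(points) <- NULL
  structure(points, class = c("landmark_set", "matrix"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Extract one landmark as a numeric vector
#' @param lm a `landmark_set`.
#' @param name landmark name.
#' @return length-3 numeric coordinate.
#' @export
landmark <- function(lm, name) {
  if (!name %in% rownames(lm)) stop("incomplete landmark set: missing ", name)
  as.numeric(lm[name, ])
}

#' @export
apply_transform.landmark_set <- function(x, transform) {
  out <- apply_transform.default(unclass(x)[, , drop = FALSE], transform)
  rownames(out) <- rownames(x)
  structure(out, class = c("landmark_set", "matrix"))
}

#' Read landmarks from JSON or CSV
#'
#' JSON files hold an object `{name: [x, y, z], ...}`; CSV files have
#' columns `name,x,y,z`. Coordinates in mm.
#'
#' @param path file path; format chosen by extension (`.json` or `.csv`).
#' @param require_all passed to [landmark_set()].
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path, require_all = TRUE) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmark_set(as.list(obj), require_all = require_all)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("landmark CSV must have columns name,x,y,z: ", path)
    }
    m <- as.matrix(df[, c("x", "y", "z")])
    rownames(m) <- df$name
    landmark_set(m, require_all = require_all)
  } else {
    stop("unsupported landmark format: ", path)
  }
}

#' Write landmarks to JSON or CSV
#' @param lm a `landmark_set`.
#' @param path output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, ]))
    names(obj) <- rownames(lm)
    jsonlite::write_json(obj, path, digits = NA)
  } else if (ext == "csv") {
    df <- data.frame(
      name = rownames(lm), x = lm[, 1], y = lm[, 2], z = lm[, 3],
      row.names = NULL
    )
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported landmark format: ", path)
  }
  invisible(path)
}
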