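#' The 21-landmark Farkas vocabulary
#'
#' Closed vocabulary of anthropometric landmark codes used throughout the
#' package. Paired landmarks carry explicit `_L`/`_R` suffixes so that left
#' and right never have to be inferred from head orientation.
#'
#' @return Character vector of the 21 landmark codes: frontotemporale
#'   (`Ft_L`/`Ft_R`), exocanthion (`Ex_L`/`Ex_R`), endocanthion
#'   (`En_L`/`En_R`), nasion (`N`), pronasale (`Prn`), subnasale (`Sn`),
#'   labiale superius (`Ls`), stomion (`Sto`), labiale inferius (`Li`),
#'   alare (`Al_L`/`Al_R`), cheilion (`Ch_L`/`Ch_R`), trichion (`Tr`),
#'   glabella (`G`), pogonion (`Pg`) and subalare (`Sbal_L`/`Sbal_R`).
#' @export
#' @examples
#' farkas_landmarks()
farkas_landmarks <- function() {
  c("Ft_L", "Ft_R", "Ex_L", "Ex_R", "En_L", "En_R", "N", "Prn", "Sn",
    "Ls", "Sto", "Li", "Al_L", "Al_R", "Ch_L", "Ch_R", "Tr", "G", "Pg",
    "Sbal_L", "Sbal_R")
}

#' Construct a landmark set
#'
#' A landmark set holds the annotated 3D coordinates (in mm) of one
#' subject's face as a tibble with one row per landmark.
#'
#' @param points Data frame with columns `landmark`, `x`, `y`, `z`
#'   (coordinates in mm).
#' @param subject_id Opaque subject identifier.
#' @param source Free-text provenance note.
#' @return A `landmark_set`: tibble with columns `landmark`, `x`, `y`, `z`
#'   and attributes `subject_id` and `source`.
#' @export
landmark_set <- function(points, subject_id = "subject", source = "") {
  pts <- as_tibble(points)
  stopifnot(all(c("landmark", "x", "y", "z") %in% names(pts)))
  pts <- pts[, c("landmark", "x", "y", "z")]
  pts$landmark <- as.character(pts$landmark)
  for (cc in c("x", "y", "z")) pts[[cc]] <- as.numeric(pts[[cc]])
  validate_landmark_set(pts)
  structure(pts, subject_id = subject_id, source = source,
            class = c("landmark_set", class(pts)))
}

validate_landmark_set <- function(pts) {
  unknown <- setdiff(pts$landmark, farkas_landmarks())
  if (length(unknown) > 0) {
    abort(paste0("Unknown landmark code(s): ", paste(unknown, collapse = ", "),
                 ". Allowed codes are the 21 Farkas landmarks; see farkas_landmarks()."))
  }
  dup <- pts$landmark[duplicated(pts$landmark)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate landmark code(s): ", paste(unique(dup), collapse = ", ")))
  }
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  if (nrow(pts) > 0 && !all(is.finite(xyz))) {
    abort("All landmark coordinates must be finite numbers.")
  }
  invisible(pts)
}

#' Read a landmark file
#'
#' Reads one subject's 3D facial landmarks from disk. Two dialects are
#' supported: a CSV file with header `landmark,x,y,z` (one landmark per
#' row, coordinates in mm), or a JSON object mapping landmark codes to
#' `[x, y, z]` arrays. Codes outside the 21-code Farkas vocabulary are
#' rejected; missing codes are allowed (distances requiring them are simply
#' not computable downstream).
#'
#' @param path Path to a `.csv` or `.json` landmark file.
#' @param subject_id Subject identifier; defaults to the file name sans
#'   extension.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("Landmark file not found: ", path))
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(obj) && !is.matrix(obj)) abort("JSON landmark file must be an object of code -> [x,y,z].")
    codes <- names(obj)
    bad <- codes[vapply(obj, function(v) length(v) != 3 || !is.numeric(v), logical(1))]
    if (length(bad) > 0) {
      abort(paste0("Landmark(s) without a numeric [x,y,z] triple: ", paste(bad, collapse = ", ")))
    }
    pts <- tibble(
      landmark = codes,
      x = map_dbl(obj, 1), y = map_dbl(obj, 2), z = map_dbl(obj, 3)
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1 || tolower(gsub("\\s", "", lines[1])) != "landmark,x,y,z") {
      abort(paste0("Landmark CSV must start with header 'landmark,x,y,z': ", path))
    }
    body <- lines[-1]
    parse_row <- function(line, lineno) {
      parts <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
      coords <- suppressWarnings(as.numeric(parts[-1]))
      if (length(parts) != 4 || anyNA(coords)) {
        abort(paste0("Malformed landmark row at line ", lineno, ": '", line, "'"))
      }
      tibble(landmark = parts[1], x = coords[1], y = coords[2], z = coords[3])
    }
    pts <- list_rbind(map2(body, seq_along(body) + 1L, parse_row))
  }
  landmark_set(pts, subject_id = subject_id, source = path)
}

#' Write a landmark set to CSV
#'
#' Inverse of [read_landmarks()] for the CSV dialect.
#'
#' @param lm A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  readr::write_csv(as_tibble(lm)[, c("landmark", "x", "y", "z")], path)
  invisible(path)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject '%s': %d of 21 landmarks\n",
              attr(x, "subject_id"), nrow(x)))
  NextMethod()
}
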