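#' Construct a triangulated face mesh
#'
#' @param vertices Numeric matrix (n x 3) of vertex coordinates in mm.
#' @param triangles Integer matrix (m x 3) of 1-based vertex indices.
#' @return A `face_mesh` object (list with `vertices` and `triangles`).
#' @export
face_mesh <- function(vertices, triangles) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(triangles); storage.mode(f) <- "integer"
  if (ncol(v) != 3 || nrow(v) < 3) abort("Mesh needs >= 3 vertices with x,y,z columns.")
  if (ncol(f) != 3 || nrow(f) < 1) abort("Mesh needs >= 1 triangle of 3 vertex indices.")
  if (!all(is.finite(v))) abort("Mesh vertices must be finite.")
  if (min(f) < 1 || max(f) > nrow(v)) {
    abort(sprintf("Triangle index out of range: vertices are 1..%d.", nrow(v)))
  }
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(degen)) {
    abort(sprintf("%d triangle(s) repeat a vertex index.", sum(degen)))
  }
  structure(list(vertices = v, triangles = f), class = "face_mesh")
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("<face_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# fan-triangulate a polygon given as vertex indices
fan_split <- function(idx) {
  if (length(idx) < 3) abort("Face with fewer than 3 vertices.")
  cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
}

#' Read a triangulated mesh
#'
#' Reads Wavefront OBJ (`v`/`f` records; `f` may carry `v/vt/vn` slashes)
#' or ascii PLY. Quads and larger polygons are fan-triangulated.
#'
#' @param path Path to a `.obj` or `.ply` file.
#' @return A [face_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort(paste0("Mesh file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (grepl("\\.ply$", path, ignore.case = TRUE) ||
      (length(lines) > 0 && trimws(lines[1]) == "ply")) {
    read_mesh_ply(lines, path)
  } else {
    read_mesh_obj(lines, path)
  }
}

read_mesh_obj <- function(lines, path) {
  toks <- strsplit(trimws(lines), "\\s+")
  vs <- list(); fs <- list()
  for (tk in toks) {
    if (length(tk) == 0) next
    if (tk[1] == "v") {
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(xyz)) abort(paste0("Non-numeric vertex in OBJ: ", path))
      vs[[length(vs) + 1]] <- xyz
    } else if (tk[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*", "", tk[-1])))
      if (anyNA(idx)) abort(paste0("Malformed face record in OBJ: ", path))
      fs[[length(fs) + 1]] <- fan_split(idx)
    }
  }
  if (length(vs) == 0 || length(fs) == 0) abort(paste0("Empty mesh: ", path))
  face_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

read_mesh_ply <- function(lines, path) {
  lines <- trimws(lines)
  if (length(lines) < 3 || lines[1] != "ply") abort(paste0("Not a PLY file: ", path))
  if (!any(grepl("^format\\s+ascii", lines))) abort("Only ascii PLY is supported.")
  end <- match("end_header", lines)
  if (is.na(end)) abort("PLY header missing end_header.")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "", grep("^element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "", grep("^element\\s+face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) abort("PLY header lacks vertex/face element counts.")
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) abort("PLY body shorter than header promises.")
  vmat <- do.call(rbind, lapply(body[seq_len(nv)], function(l) {
    xyz <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]][1:3]))
    if (anyNA(xyz)) abort(paste0("Non-numeric PLY vertex: ", path))
    xyz
  }))
  fmat <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(l) {
    tk <- suppressWarnings(as.integer(strsplit(l, "\\s+")[[1]]))
    if (anyNA(tk) || length(tk) < 4 || tk[1] != length(tk) - 1) {
      abort(paste0("Malformed PLY face record: '", l, "'"))
    }
    fan_split(tk[-1] + 1L)  # PLY indices are 0-based
  }))
  face_mesh(vmat, fmat)
}

#' Write a mesh to OBJ or ascii PLY
#'
#' Format is chosen from the file extension (`.obj` or `.ply`).
#'
#' @param mesh A [face_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "face_mesh"))
  v <- mesh$vertices; f <- mesh$triangles
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property float x", "property float y", "property float z",
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(header, vl, fl), path)
  } else {
    vl <- sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(vl, fl), path)
  }
  invisible(path)
}
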