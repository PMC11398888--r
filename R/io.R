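#' Read and write triangle meshes (OFF and ASCII PLY)
#'
#' Minimal readers/writers for the two standard text dialects. OFF files
#' start with the "OFF" magic and a vertex/face/edge count line; PLY files
#' are the ASCII 1.0 dialect with vertex properties x, y, z and face lists
#' of length 3.
#'
#' @param path file path; format is chosen by extension for
#'   \code{read_mesh}/\code{write_mesh}.
#' @return \code{read_*} return a \code{fos_mesh}; \code{write_*} return
#'   the path invisibly.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1L]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  s <- counts[1L]
  t <- counts[2L]
  vl <- lines[2L + seq_len(s)]
  fl <- lines[2L + s + seq_len(t)]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[1:3])))
  fr <- lapply(strsplit(fl, "\\s+"), as.integer)
  if (any(vapply(fr, `[`, 1L, 1L) != 3L))
    stop("only triangle faces are supported")
  f <- do.call(rbind, lapply(fr, function(x) x[2:4]))
  fos_mesh(v, f)
}

# exact decimal text for doubles: %.17g round trips bitwise
fmt_rows <- function(M) {
  apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
}

#' @rdname mesh_io
#' @param mesh a \code{fos_mesh}.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(fmt_rows(mesh$vertices), con)
  utils::write.table(cbind(3L, mesh$faces), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1L]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format", hdr, value = TRUE)
  if (!grepl("ascii", fmt))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)))
  body <- trimws(lines[-seq_len(hdr_end)])
  body <- body[nzchar(body)]
  v <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
                             function(x) as.numeric(x[1:3])))
  fr <- lapply(strsplit(body[nv + seq_len(nf)], "\\s+"), as.integer)
  if (any(vapply(fr, `[`, 1L, 1L) != 3L))
    stop("only triangle faces are supported")
  f <- do.call(rbind, lapply(fr, function(x) x[2:4]))
  fos_mesh(v, f)
}

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n_vertices(mesh)),
               "property double x", "property double y",
               "property double z",
               sprintf("element face %d", n_faces(mesh)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(fmt_rows(mesh$vertices), con)
  utils::write.table(cbind(3L, mesh$faces), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         off = read_off(path), ply = read_ply(path),
         stop("unsupported mesh format: ", path))
}

#' @rdname mesh_io
#' @export
write_mesh <- function(mesh, path) {
  switch(tolower(tools::file_ext(path)),
         off = write_off(mesh, path), ply = write_ply(mesh, path),
         stop("unsupported mesh format: ", path))
}

#' Read and write vertex functions
#'
#' Headered tab-delimited text with columns \code{vertex_index} (0-based)
#' and \code{value}. A multi-map container variant stores one column per
#' subject (\code{write_vertex_functions}) for whole datasets.
#'
#' @param path file path.
#' @param mesh the carrying \code{fos_mesh}.
#' @return a \code{vertex_function} (or list of them).
#' @name vertex_function_io
NULL

#' @rdname vertex_function_io
#' @export
read_vertex_function <- function(path, mesh) {
  tab <- utils::read.delim(path)
  vals <- numeric(n_vertices(mesh))
  vals[tab$vertex_index + 1L] <- tab$value
  vertex_function(vals, mesh)
}

#' @rdname vertex_function_io
#' @param f a \code{vertex_function}.
#' @export
write_vertex_function <- function(f, path) {
  vals <- if (inherits(f, "vertex_function")) f$values else as.numeric(f)
  writeLines(c("vertex_index\tvalue",
               sprintf("%d\t%.17g", seq_along(vals) - 1L, vals)), path)
  invisible(path)
}

#' @rdname vertex_function_io
#' @param fs list of \code{vertex_function}s on one mesh.
#' @export
write_vertex_functions <- function(fs, path) {
  vals <- do.call(cbind, lapply(fs, `[[`, "values"))
  hdr <- paste(c("vertex_index", sprintf("subject_%03d", seq_along(fs))),
               collapse = "\t")
  rows <- sprintf("%d\t%s", seq_len(nrow(vals)) - 1L,
                  apply(vals, 1L, function(r)
                    paste(sprintf("%.17g", r), collapse = "\t")))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname vertex_function_io
#' @export
read_vertex_functions <- function(path, mesh) {
  tab <- utils::read.delim(path)
  cols <- setdiff(names(tab), "vertex_index")
  lapply(cols, function(cn) {
    vals <- numeric(n_vertices(mesh))
    vals[tab$vertex_index + 1L] <- tab[[cn]]
    vertex_function(vals, mesh)
  })
}

#' Read and write velocity fields
#'
#' Delimited table of control-point coordinates and coefficients, with a
#' small comment header recording the kernel bandwidth and type.
#'
#' @param path file path.
#' @name velocity_io
NULL

#' @rdname velocity_io
#' @param v a \code{velocity_field}.
#' @export
write_velocity_field <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kernel: %s", v$kernel$type),
               sprintf("# sigma: %.17g", v$kernel$sigma)), con)
  writeLines("cx\tcy\tcz\tax\tay\taz", con)
  M <- cbind(v$control_points, v$coefficients)
  writeLines(apply(M, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname velocity_io
#' @export
read_velocity_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  sigma <- as.numeric(sub("^# sigma:\\s*", "",
                          grep("^# sigma:", hdr, value = TRUE)))
  tab <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                               invert = TRUE)))
  velocity_field(as.matrix(tab[, c("cx", "cy", "cz")]),
                 as.matrix(tab[, c("ax", "ay", "az")]),
                 kernel_spec(sigma))
}
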