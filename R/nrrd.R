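# NRRD (.nrrd, single-file) reader and writer.
#
# Header is plain text, data follows the first blank line. Supported: 3-D
# arrays, raw or gzip encodings, little/big endian, LPS or RAS space (RAS is
# converted to the package's LPS convention on read). Written files use
# gzip encoding, little endian, LPS space.

NRRD_TYPES <- list(
  "uint8"   = list(what = "integer", size = 1, signed = FALSE),
  "uchar"   = list(what = "integer", size = 1, signed = FALSE),
  "int8"    = list(what = "integer", size = 1, signed = TRUE),
  "int16"   = list(what = "integer", size = 2, signed = TRUE),
  "short"   = list(what = "integer", size = 2, signed = TRUE),
  "uint16"  = list(what = "integer", size = 2, signed = FALSE),
  "int32"   = list(what = "integer", size = 4, signed = TRUE),
  "int"     = list(what = "integer", size = 4, signed = TRUE),
  "float"   = list(what = "double",  size = 4, signed = TRUE),
  "double"  = list(what = "double",  size = 8, signed = TRUE)
)

parse_nrrd_vectors <- function(s) {
  # "(a,b,c) (d,e,f) ..." -> list of numeric vectors; "none" entries skipped
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  if (m[1] == -1) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  lapply(seq_along(starts), function(t) {
    inner <- substr(s, starts[t] + 1, starts[t] + lens[t] - 2)
    as.numeric(strsplit(inner, ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  bytes <- readBin(con, "raw", file.info(path)$size + 16)
  # header ends at the first blank line (\n\n or \r\n\r\n)
  nl2 <- which(bytes[-length(bytes)] == as.raw(10) &
               bytes[-1] == as.raw(10))
  if (!length(nl2))
    stop("not a NRRD file (no header terminator): ", path, call. = FALSE)
  hdr_end <- nl2[1]
  header <- rawToChar(bytes[seq_len(hdr_end)])
  data_raw <- bytes[(hdr_end + 2):length(bytes)]

  lines <- strsplit(header, "\r?\n")[[1]]
  if (!grepl("^NRRD000", lines[1]))
    stop("not a NRRD file (bad magic): ", path, call. = FALSE)
  lines <- lines[-1]
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0) next
    key <- tolower(trimws(substr(ln, 1, pos - 1)))
    val <- trimws(sub("^=", "", trimws(substring(ln, pos + 1))))
    kv[[key]] <- val
  }

  ndim <- as.integer(kv[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("expected a 3D NRRD, got dimension ", kv[["dimension"]], ": ", path,
         call. = FALSE)
  sizes <- as.integer(strsplit(kv[["sizes"]], "[[:space:]]+")[[1]])
  tinfo <- NRRD_TYPES[[tolower(kv[["type"]])]]
  if (is.null(tinfo))
    stop("unsupported NRRD type '", kv[["type"]], "': ", path, call. = FALSE)
  encoding <- tolower(if (is.null(kv[["encoding"]])) "raw" else kv[["encoding"]])
  endian <- tolower(if (is.null(kv[["endian"]])) "little" else kv[["endian"]])

  if (encoding %in% c("gzip", "gz")) {
    data_raw <- memDecompress(data_raw, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding '", encoding, "': ", path, call. = FALSE)
  }
  nvox <- prod(sizes)
  vals <- readBin(data_raw, tinfo$what, n = nvox, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NRRD voxel data: ", path, call. = FALSE)

  space <- tolower(if (is.null(kv[["space"]])) "" else kv[["space"]])
  dirs <- parse_nrrd_vectors(if (is.null(kv[["space directions"]])) ""
                             else kv[["space directions"]])
  org <- parse_nrrd_vectors(if (is.null(kv[["space origin"]])) ""
                            else kv[["space origin"]])
  if (length(dirs) == 3 && all(lengths(dirs) == 3)) {
    M <- do.call(cbind, dirs)
  } else if (!is.null(kv[["spacings"]])) {
    M <- diag(as.numeric(strsplit(kv[["spacings"]], "[[:space:]]+")[[1]]))
  } else {
    M <- diag(3)
  }
  origin <- if (length(org) == 1 && length(org[[1]]) == 3) org[[1]] else
    c(0, 0, 0)
  flip <- c("right-anterior-superior", "ras")
  if (space %in% flip) {                 # RAS -> LPS
    M[1:2, ] <- -M[1:2, ]
    origin[1:2] <- -origin[1:2]
  }
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  image_volume(array(vals, sizes), spacing = spacing, origin = origin,
               direction = direction)
}

write_nrrd <- function(vol, path) {
  stopifnot_volume(vol)
  dt <- nifti_datatype_for(vol$data)     # same promotion rules as NIfTI
  type <- switch(as.character(dt$code), "2" = "uint8", "4" = "int16",
                 "8" = "int32", "64" = "double")
  M <- vol$direction %*% diag(vol$spacing)
  fmt <- function(v) paste0("(", paste(format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE),
                                       collapse = ","), ")")
  header <- c(
    "NRRD0004",
    "# generated by aortaquant",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(vol$data), collapse = " ")),
    paste0("space directions: ", paste(fmt(M[, 1]), fmt(M[, 2]), fmt(M[, 3]))),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    paste0("space origin: ", fmt(vol$origin)),
    "")
  vals <- as.vector(vol$data)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  payload <- memCompress(writeBin(vals, raw(), size = dt$size,
                                  endian = "little"), type = "gzip")
  con <- tryCatch(file(path, "wb"),
    error = function(e) stop("cannot open for writing: ", path, call. = FALSE),
    warning = function(w) stop("cannot open for writing: ", path,
                               call. = FALSE))
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}
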