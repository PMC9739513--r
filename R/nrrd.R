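# Minimal NRRD reader/writer. Covers the subset this package emits and the
# plain scalar-volume files produced by common research tools: 3D data,
# little-endian, `raw` or `gzip` encoding, spacing given either as `spacings`
# or diagonal `space directions`. NRRD stores the fastest axis first (x),
# so arrays are reordered into the internal (z, y, x) convention on read.

nrrd_type_map <- c(
  "signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "short" = "int16", "short int" = "int16", "int16" = "int16",
  "ushort" = "uint16", "unsigned short" = "uint16", "uint16" = "uint16",
  "int" = "int32", "signed int" = "int32", "int32" = "int32",
  "float" = "float", "double" = "double"
)

nrrd_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("expected 3D NRRD data, got dimension ", fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)))
    stop("missing spacing metadata in NRRD header of ", path)
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.info(path)$size)
  enc <- tolower(fields[["encoding"]])
  if (enc == "gzip" || enc == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  what <- switch(type,
    int8 = , uint8 = "integer",
    int16 = , uint16 = , int32 = "integer",
    float = , double = "double")
  size_bytes <- switch(type, int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
                       int32 = 4L, float = 4L, double = 8L)
  signed <- !type %in% c("uint8", "uint16")
  vals <- readBin(payload, what, n = n, size = size_bytes, signed = signed,
                  endian = "little")
  if (length(vals) != n) stop("truncated NRRD payload in ", path)
  arr <- array(as.numeric(vals), dim = sizes)      # (x, y, z), x fastest
  new_volume(aperm(arr, c(3, 2, 1)), spacing_mm = rev(spacing))
}

nrrd_write <- function(volume, path, encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  arr <- aperm(volume$values, c(3, 2, 1))          # back to (x, y, z)
  header <- c(
    "NRRD0004",
    "# generated by ggnrad",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
    sprintf("spacings: %.10g %.10g %.10g",
            volume$spacing_mm[3], volume$spacing_mm[2], volume$spacing_mm[1]),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  payload <- writeBin(as.numeric(arr), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}
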