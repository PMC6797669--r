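#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha`, `.mhd`). All volumes are presented in a single fixed RAS world
#' frame (mm): NIfTI s/qforms are RAS natively; MetaImage headers use the
#' ITK LPS convention and are converted on read (and back on write) by
#' flipping the first two world axes.
#'
#' @param path path to the volume file.
#' @return A [us_volume()] with geometry populated from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop("unreadable NIfTI file: ", path,
                                             " (", conditionMessage(e), ")"))
    m <- RNifti::xform(img)
    d <- dim(img)
    if (length(d) != 3L) stop("expected a 3D volume in ", path)
    sp <- sqrt(colSums(m[1:3, 1:3]^2))
    if (any(sp <= 0) || any(!is.finite(sp)))
      stop("missing or invalid spacing in NIfTI header: ", path)
    ori <- m[1:3, 1:3] %*% diag(1 / sp)
    us_volume(array(as.numeric(img), d), spacing = sp, origin = m[1:3, 4],
              orientation = ori)
  } else if (ext %in% c(".mha", ".mhd")) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format (need .nii[.gz], .mha or .mhd): ", path)
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Intensities are stored as 32-bit floats. Reading the file back
#' reproduces integer-valued data bit-exactly and floating data to single
#' precision (better than 1e-6 relative).
#'
#' @param v a [us_volume()] or [us_mask()].
#' @param path destination; format chosen from the extension
#'   (`.nii`/`.nii.gz`/`.mha`/`.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "us_volume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume, directory does not exist: ", dirname(path))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::asNifti(array(as.numeric(v$data), dim(v$data)))
    RNifti::pixdim(img) <- v$spacing
    m <- rbind(cbind(v$orientation %*% diag(v$spacing), v$origin), c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(v, path)
  } else {
    stop("unsupported volume format (need .nii[.gz], .mha or .mhd): ", path)
  }
  invisible(path)
}

# --- MetaImage (MHA/MHD), the text-headed ITK format. LPS world frame. ----

ras_flip <- diag(c(-1, -1, 1))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); data_file <- NULL
  parse_fail <- function(...) stop("unreadable MetaImage header in ", path)
  tryCatch(withCallingHandlers(
    repeat {
      line <- readLines(con, n = 1L, warn = FALSE, skipNul = TRUE)
      if (length(line) == 0L) parse_fail()
      kv <- regmatches(line, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", line,
                                     useBytes = TRUE))[[1]]
      if (length(kv) != 3L) parse_fail()
      hdr[[kv[2]]] <- trimws(kv[3])
      if (kv[2] == "ElementDataFile") { data_file <- hdr[[kv[2]]]; break }
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = parse_fail)
  if (!identical(hdr$ObjectType, "Image") || !identical(hdr$NDims, "3"))
    stop("unsupported MetaImage (need 3D Image): ", path)
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage not supported: ", path)
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "", "\\s+")[[1]])
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid ElementSpacing in ", path)
  off <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1", "\\s+")[[1]])
  dir_lps <- matrix(tm, 3, 3)  # columns = image axis directions in LPS
  type <- hdr$ElementType %||% "MET_FLOAT"
  sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
             MET_UINT = 4L, MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)
  if (!type %in% names(sizes)) stop("unsupported ElementType ", type, " in ", path)
  n <- prod(d)
  if (identical(data_file, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), data_file), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
  vals <- suppressWarnings(readBin(raw_con, what = what, n = n, size = sizes[[type]],
                  signed = !(type %in% c("MET_UCHAR", "MET_USHORT")),
                  endian = if (identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE")) "big" else "little"))
  if (length(vals) != n) stop("truncated MetaImage data in ", path)
  us_volume(array(as.numeric(vals), d),
            spacing = sp,
            origin = as.numeric(ras_flip %*% off),
            orientation = ras_flip %*% dir_lps)
}

write_metaimage <- function(v, path) {
  dir_lps <- ras_flip %*% v$orientation
  off_lps <- as.numeric(ras_flip %*% v$origin)
  is_mhd <- grepl("\\.mhd$", tolower(path))
  data_name <- if (is_mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(as.numeric(dir_lps), digits = 17), collapse = " ")),
    paste("Offset =", paste(format(off_lps, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(v$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(dim(v$data), collapse = " ")),
    "ElementType = MET_FLOAT",
    paste("ElementDataFile =", data_name))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.numeric(v$data), raw(), size = 4L, endian = "little")
  if (is_mhd) {
    raw_con <- file(file.path(dirname(path), data_name), "wb")
    writeBin(payload, raw_con)
    close(raw_con)
  } else {
    writeBin(payload, con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read landmarks from CSV or MNI tag files
#'
#' The canonical dialect is CSV with header `label,x,y,z` and world-mm
#' coordinates. The MNI `.tag` dialect (as shipped with the public RESECT
#' and BITE datasets) is supported read-only; a two-volume tag file yields
#' a pair of equally sized, order-matched sets.
#'
#' @param path landmark file.
#' @param dialect `"csv"` or `"mni_tag"`.
#' @return A [landmark_set()]; for a two-volume tag file, a list of two
#'   landmark sets named `ref` and `other`.
#' @export
read_landmarks <- function(path, dialect = c("csv", "mni_tag")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("landmark file does not exist: ", path)
  if (dialect == "csv") {
    lines <- readLines(path)
    if (length(lines) < 1L || tolower(gsub("\\s", "", lines[1])) != "label,x,y,z")
      stop("landmark CSV must start with header 'label,x,y,z': ", path)
    rows <- strsplit(lines[-1], ",")
    rows <- rows[vapply(rows, length, 0L) > 0L]
    pts <- matrix(NA_real_, length(rows), 3)
    labs <- character(length(rows))
    for (i in seq_along(rows)) {
      r <- trimws(rows[[i]])
      if (length(r) != 4L)
        stop("landmark CSV line ", i + 1L, ": expected 4 fields, got ", length(r))
      xyz <- suppressWarnings(as.numeric(r[2:4]))
      if (any(is.na(xyz)))
        stop("landmark CSV line ", i + 1L, ": non-numeric coordinate")
      labs[i] <- r[1]; pts[i, ] <- xyz
    }
    landmark_set(pts, labs)
  } else {
    lines <- readLines(path)
    pstart <- grep("^\\s*Points\\s*=", lines)
    if (length(pstart) != 1L) stop("no 'Points =' block in tag file: ", path)
    body <- lines[(pstart + 1L):length(lines)]
    body <- sub(";\\s*$", "", body)
    body <- body[nzchar(trimws(body))]
    n_per_row <- NULL
    p1 <- list(); p2 <- list(); labs <- character()
    for (i in seq_along(body)) {
      labs[i] <- if (grepl("\"", body[i]))
        sub("^.*\"(.*)\".*$", "\\1", body[i]) else paste0("L", i)
      nums <- suppressWarnings(as.numeric(
        strsplit(trimws(gsub("\"[^\"]*\"", "", body[i])), "\\s+")[[1]]))
      if (any(is.na(nums)) || !(length(nums) %in% c(3L, 6L)))
        stop("tag file line ", pstart + i, ": expected 3 or 6 numeric coordinates")
      if (is.null(n_per_row)) n_per_row <- length(nums)
      if (length(nums) != n_per_row)
        stop("tag file has unequal set sizes: row ", i, " has ", length(nums) / 3,
             " point(s) but earlier rows have ", n_per_row / 3)
      p1[[i]] <- nums[1:3]
      if (n_per_row == 6L) p2[[i]] <- nums[4:6]
    }
    if (length(p1) == 0L) stop("empty Points block in tag file: ", path)
    ref <- landmark_set(do.call(rbind, p1), labs)
    if (n_per_row == 6L)
      list(ref = ref, other = landmark_set(do.call(rbind, p2), labs))
    else ref
  }
}

#' Write landmarks to CSV (`label,x,y,z`, mm)
#'
#' @param lm a [landmark_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  writeLines(c("label,x,y,z",
               sprintf("%s,%.17g,%.17g,%.17g", attr(lm, "labels"),
                       lm[, 1], lm[, 2], lm[, 3])), con, sep = "\n")
  invisible(path)
}

#' Serialize a transform chain to YAML
#'
#' Rigid steps store their parameters inline (translation mm, intrinsic XYZ
#' Euler angles rad, center mm) together with the world frame they are
#' expressed in; deformation fields are written as 3-component NIfTI
#' displacement volumes (mm) referenced from the YAML document.
#'
#' @param chain a [transform_chain()].
#' @param path destination `.yaml` file; field volumes are written next to it.
#' @return `path`, invisibly.
#' @export
write_transform_chain <- function(chain, path) {
  stopifnot(inherits(chain, "transform_chain"))
  steps <- list(); fid <- 0L
  for (s in chain) {
    if (inherits(s, "rigid_transform")) {
      steps[[length(steps) + 1L]] <- list(
        type = "rigid", frame = "world_ras",
        translation_mm = as.numeric(s$translation),
        rotation_rad = as.numeric(s$rotation),
        center_mm = as.numeric(s$center))
    } else {
      fid <- fid + 1L
      fname <- sprintf("%s_field%02d.nii.gz",
                       sub("\\.ya?ml$", "", basename(path)), fid)
      img <- RNifti::asNifti(array(as.numeric(s$disp), dim(s$disp)))
      RNifti::pixdim(img) <- c(s$spacing, 1)
      m <- rbind(cbind(s$orientation %*% diag(s$spacing), s$origin), c(0, 0, 0, 1))
      img <- RNifti::`sform<-`(img, structure(m, code = 2L))
      RNifti::writeNifti(img, file.path(dirname(path), fname),
                         datatype = "float")
      steps[[length(steps) + 1L]] <- list(
        type = "field", frame = "world_ras", units = "mm",
        displacement_file = fname)
    }
  }
  yaml::write_yaml(list(transform_chain = steps), path)
  invisible(path)
}

#' Read a transform chain written by [write_transform_chain()]
#'
#' @param path the `.yaml` file.
#' @return A [transform_chain()].
#' @export
read_transform_chain <- function(path) {
  if (!file.exists(path)) stop("chain file does not exist: ", path)
  doc <- yaml::read_yaml(path)
  steps <- lapply(doc$transform_chain, function(s) {
    if (identical(s$type, "rigid")) {
      rigid_transform(s$translation_mm, s$rotation_rad, s$center_mm)
    } else if (identical(s$type, "field")) {
      img <- RNifti::readNifti(file.path(dirname(path), s$displacement_file))
      m <- RNifti::xform(img)
      sp <- sqrt(colSums(m[1:3, 1:3]^2))
      deformation_field(array(as.numeric(img), dim(img)), spacing = sp,
                        origin = m[1:3, 4],
                        orientation = m[1:3, 1:3] %*% diag(1 / sp))
    } else stop("unknown chain step type: ", s$type)
  })
  transform_chain(steps)
}
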