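# OME metadata lives in a companion OME-XML file next to the TIFF (the
# libtiff wrapper used here cannot write an ImageDescription tag). Intensities
# are stored as 32-bit floats scaled into [0,1]; the scale factor is recorded
# in the companion XML and undone on read.

companion_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".companion.ome.xml")

#' Write an ImageVolume or ImageTimelapse as TIFF + companion OME-XML
#'
#' Pages are written in XYZCT order (z fastest, then channel, then time). The
#' companion file records SizeX/Y/Z/C/T, channel names, PhysicalSizeX/Y/Z in
#' um, the frame interval (TimeIncrement, seconds) and the intensity scale
#' factor used to map counts into the unit interval of the float TIFF.
#'
#' @param volume an [image_volume()] or [image_timelapse()].
#' @param path output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "ImageTimelapse")) {
    frames <- volume$frames
    frame_interval <- volume$frame_interval
  } else if (inherits(volume, "ImageVolume")) {
    frames <- list(volume)
    frame_interval <- volume$frame_interval
  } else stop("write_volume expects an ImageVolume or ImageTimelapse")
  ref <- frames[[1L]]
  chs <- names(ref$channels)
  d <- dim(ref$channels[[1L]])
  nz <- if (length(d) == 3L) d[3L] else 1L
  vs <- ref$voxel_size
  scale <- max(1, max(vapply(frames, function(f) max(unlist(f$channels)), numeric(1))))

  pages <- list()
  for (f in frames) {
    for (ch in chs) {
      arr <- f$channels[[ch]]
      if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
      for (k in seq_len(nz)) pages[[length(pages) + 1L]] <- arr[, , k] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)

  doc <- xml2::xml_new_root("OME")
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0")
  px_attrs <- list(ID = "Pixels:0", DimensionOrder = "XYZCT", Type = "float",
                   SizeX = d[2L], SizeY = d[1L], SizeZ = nz,
                   SizeC = length(chs), SizeT = length(frames),
                   PhysicalSizeX = vs[["x"]], PhysicalSizeY = vs[["y"]])
  if ("z" %in% names(vs)) px_attrs$PhysicalSizeZ <- vs[["z"]]
  if (!is.null(frame_interval)) px_attrs$TimeIncrement <- frame_interval
  px <- xml2::xml_add_child(img, "Pixels")
  for (a in names(px_attrs)) xml2::xml_set_attr(px, a, as.character(px_attrs[[a]]))
  for (i in seq_along(chs)) {
    xml2::xml_add_child(px, "Channel", ID = paste0("Channel:", i - 1L),
                        Name = chs[i])
  }
  ann <- xml2::xml_add_child(doc, "StructuredAnnotations")
  xa <- xml2::xml_add_child(ann, "XMLAnnotation", ID = "Annotation:0")
  val <- xml2::xml_add_child(xa, "Value")
  sf <- xml2::xml_add_child(val, "ScaleFactor")
  xml2::xml_set_text(sf, format(scale, digits = 17))
  xml2::write_xml(doc, companion_path(path))
  invisible(path)
}

#' Read a TIFF (+ companion OME-XML) volume or time-lapse
#'
#' Reconstructs channels, z planes and time points from the companion
#' metadata written by [write_volume()]. Without companion metadata the file
#' is treated as a single-channel stack and `voxel_size` must be supplied; a
#' missing physical voxel size with no override is an error.
#'
#' @param path TIFF path.
#' @param voxel_size optional override, named `c(x=, y=)` or `c(x=, y=, z=)`.
#' @param frame_interval optional override, seconds.
#' @return An [image_volume()], or an [image_timelapse()] when SizeT > 1.
#' @export
read_volume <- function(path, voxel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  comp <- companion_path(path)
  if (file.exists(comp)) {
    doc <- xml2::read_xml(comp)
    px <- xml2::xml_find_first(doc, ".//Pixels")
    att <- function(a) xml2::xml_attr(px, a)
    nz <- as.integer(att("SizeZ")); nc <- as.integer(att("SizeC"))
    nt <- as.integer(att("SizeT"))
    chs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
    if (is.null(voxel_size)) {
      psx <- suppressWarnings(as.numeric(att("PhysicalSizeX")))
      psy <- suppressWarnings(as.numeric(att("PhysicalSizeY")))
      psz <- suppressWarnings(as.numeric(att("PhysicalSizeZ")))
      if (is.na(psx) || is.na(psy) || (nz > 1L && is.na(psz))) {
        stop("missing PhysicalSizeX/Y", if (nz > 1L) "/Z",
             " in metadata and no voxel_size override supplied")
      }
      voxel_size <- if (nz > 1L || !is.na(psz)) c(x = psx, y = psy, z = psz) else
        c(x = psx, y = psy)
    }
    if (is.null(frame_interval)) {
      ti <- suppressWarnings(as.numeric(att("TimeIncrement")))
      if (!is.na(ti)) frame_interval <- ti
    }
    sc_node <- xml2::xml_find_first(doc, ".//ScaleFactor")
    scale <- if (inherits(sc_node, "xml_missing")) 1 else
      as.numeric(xml2::xml_text(sc_node))
  } else {
    if (is.null(voxel_size)) {
      stop("no companion metadata found for '", path,
           "': physical voxel size unknown; supply voxel_size = c(x=, y=, ...)")
    }
    nz <- length(pages); nc <- 1L; nt <- 1L; chs <- "ch1"; scale <- 1
  }
  voxel_size <- unlist(voxel_size)
  if (length(pages) != nz * nc * nt) {
    stop("page count (", length(pages), ") does not match SizeZ*SizeC*SizeT")
  }
  mk_frame <- function(t_idx) {
    channels <- setNames(vector("list", nc), chs)
    for (c_idx in seq_len(nc)) {
      planes <- lapply(seq_len(nz), function(z_idx) {
        pages[[(t_idx - 1L) * nc * nz + (c_idx - 1L) * nz + z_idx]] * scale
      })
      arr <- if (nz == 1L) planes[[1L]] else
        array(unlist(planes), dim = c(dim(planes[[1L]]), nz))
      channels[[c_idx]] <- arr
    }
    vs <- if (nz == 1L) voxel_size[c("x", "y")] else voxel_size[c("x", "y", "z")]
    image_volume(channels, voxel_size = vs, frame_interval = frame_interval)
  }
  if (nt == 1L) return(mk_frame(1L))
  image_timelapse(lapply(seq_len(nt), mk_frame), frame_interval)
}

#' Write a measurement table as CSV with provenance
#'
#' One row per object/cell/track, floats serialised with full (17 significant
#' digit) precision, preceded by a `#`-prefixed provenance line carrying the
#' package version and, when a config is given, its hash.
#'
#' @param records data frame (a list of data frames with identical schemas is
#'   row-bound; differing schemas are rejected).
#' @param path output path.
#' @param config optional `PipelineConfig` whose hash is embedded.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, config = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    schemas <- unique(vapply(records, function(r) paste(names(r), collapse = ","),
                             character(1)))
    if (length(schemas) > 1L) stop("records have mixed schemas: ",
                                   paste(schemas, collapse = " vs "))
    records <- do.call(rbind, records)
  }
  stopifnot(is.data.frame(records))
  prov <- paste0("# mitoquant ", as.character(packageVersion("mitoquant")),
                 if (!is.null(config)) paste0(" config ", config_hash(config)))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path CSV path.
#' @return Data frame (provenance line available as attribute `"provenance"`).
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "#")) attr(df, "provenance") <- sub("^#\\s*", "", first)
  df
}
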