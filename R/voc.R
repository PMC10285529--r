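#' Read Pascal-VOC-style bounding-box annotations
#'
#' Each XML file holds one image's objects (`<object><name/><bndbox>` with
#' `xmin`, `ymin`, `xmax`, `ymax`). VOC boxes are 1-based inclusive with `x`
#' along columns and `y` along rows; ingestion converts them to the package's
#' 0-based half-open convention (`rmin = ymin - 1`, `rmax = ymax`, etc.) so
#' box areas equal pixel counts.
#'
#' @param path One or more XML files, or a directory (all `*.xml` inside).
#' @return Tibble with `source_id`, `label`, `rmin`, `cmin`, `rmax`, `cmax`.
#' @export
read_voc_annotations <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.xml$", full.names = TRUE)
  } else {
    path
  }
  purrr::map_dfr(files, function(f) {
    doc <- xml2::read_xml(f)
    fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
    if (is.na(fname) || fname == "") fname <- basename(f)
    objs <- xml2::xml_find_all(doc, ".//object")
    if (length(objs) == 0L) {
      return(tibble::tibble(source_id = character(), label = character(),
                            rmin = integer(), cmin = integer(),
                            rmax = integer(), cmax = integer()))
    }
    purrr::map_dfr(objs, function(o) {
      num <- function(tag) {
        as.integer(round(as.numeric(
          xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))))
      }
      xmin <- num("xmin"); ymin <- num("ymin")
      xmax <- num("xmax"); ymax <- num("ymax")
      if (any(is.na(c(xmin, ymin, xmax, ymax))) ||
          xmin > xmax || ymin > ymax) {
        stop(sprintf("structural error: invalid bndbox in %s", f),
             call. = FALSE)
      }
      tibble::tibble(
        source_id = fname,
        label = xml2::xml_text(xml2::xml_find_first(o, ".//name")),
        rmin = ymin - 1L, cmin = xmin - 1L, rmax = ymax, cmax = xmax
      )
    })
  })
}

#' Write bounding boxes as a Pascal-VOC-style XML file
#'
#' The inverse of [read_voc_annotations()]: boxes in the 0-based half-open
#' convention are serialized as 1-based inclusive VOC coordinates.
#'
#' @param boxes Tibble with `label`, `rmin`, `cmin`, `rmax`, `cmax`.
#' @param path Output XML path.
#' @param filename Image file name recorded in the annotation.
#' @param dim Image dimensions `c(nrow, ncol)` for the `<size>` block.
#' @return `path`, invisibly.
#' @export
write_voc_annotations <- function(boxes, path, filename, dim) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(dim[2]))
  xml2::xml_add_child(size, "height", as.character(dim[1]))
  xml2::xml_add_child(size, "depth", "2")
  for (i in seq_len(nrow(boxes))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", boxes$label[i])
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(boxes$cmin[i] + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(boxes$rmin[i] + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(boxes$cmax[i]))
    xml2::xml_add_child(bb, "ymax", as.character(boxes$rmax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
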