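# Composite (lobar-level) region definitions and their IO.

#' Construct a region map
#'
#' A region map lists the composites into which atlas regions are combined:
#' thickness composites are averaged (a mean of means-per-region thickness is
#' still a thickness), segmentation-volume composites are summed. The
#' aggregation rule is therefore tied to the measure class and validated
#' here.
#'
#' @param composites list of composites, each a list with fields `name`,
#'   `hemisphere` ("L", "R" or "bilateral"), `members` (character vector of
#'   region names), `aggregation` ("mean"/"sum") and `measure_class`.
#' @return an object of class `region_map`.
#' @export
region_map <- function(composites) {
  nm <- vapply(composites, `[[`, "", "name")
  abort_if(anyDuplicated(nm) > 0, "duplicate composite names")
  for (cmp in composites) {
    abort_if(length(cmp$members) == 0, "empty member set in ", cmp$name)
    abort_if(!cmp$hemisphere %in% c("L", "R", "bilateral"),
             "bad hemisphere in ", cmp$name)
    abort_if(!cmp$measure_class %in% MEASURE_CLASSES,
             "bad measure_class in ", cmp$name)
    ok <- (cmp$aggregation == "mean" && cmp$measure_class == "cortical_thickness") ||
      (cmp$aggregation == "sum" && cmp$measure_class %in% VOLUME_CLASSES)
    abort_if(!ok, "composite ", cmp$name,
             ": aggregation must be 'mean' for cortical_thickness and 'sum' for volumes")
  }
  names(composites) <- nm
  structure(composites, class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>", length(x), "composites\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.region_map <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, "", "name"),
             hemisphere = vapply(x, `[[`, "", "hemisphere"),
             n_members = vapply(x, function(c) length(c$members), 0L),
             aggregation = vapply(x, `[[`, "", "aggregation"),
             measure_class = vapply(x, `[[`, "", "measure_class"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite names of a region map
#' @param map a `region_map`.
#' @param measure_class optionally restrict to one measure class.
#' @return character vector.
#' @export
composite_names <- function(map, measure_class = NULL) {
  nm <- vapply(map, `[[`, "", "name")
  if (!is.null(measure_class))
    nm <- nm[vapply(map, `[[`, "", "measure_class") %in% measure_class]
  unname(nm)
}

#' Read / write region maps (YAML or JSON, chosen by file extension)
#' @param path file path ending in .yaml/.yml or .json.
#' @return a `region_map` (for the reader); `path` invisibly (for the writer).
#' @export
read_region_map <- function(path) {
  abort_if(!file.exists(path), "no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  region_map(lapply(raw$composites, function(cmp) {
    cmp$members <- unlist(cmp$members)
    cmp
  }))
}

#' @rdname read_region_map
#' @param map a `region_map`.
#' @export
write_region_map <- function(map, path) {
  payload <- list(schema = "zmapendo/region_map/1",
                  composites = lapply(unclass(map), function(cmp)
                    cmp[c("name", "hemisphere", "members", "aggregation",
                          "measure_class")]))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(payload, path)
  invisible(path)
}

# --- Atlas label sets -------------------------------------------------------

#' Desikan-Killiany cortical labels and their lobar assignment
#'
#' The 34 gyral labels of the Desikan-Killiany parcellation, partitioned into
#' the composites used throughout: the frontal lobe is split into a
#' pre-motor/motor part and the non-motor remainder, parietal / temporal /
#' occipital lobes are kept whole, and cingulate, parahippocampal, entorhinal
#' and insular cortex form a limbic composite. The exact membership is a
#' documented reconstruction and fully user-overridable via custom region
#' maps.
#'
#' @return named list of character vectors of DK labels.
#' @export
dk_lobe_assignment <- function() {
  list(
    frontal_motor = c("precentral", "paracentral", "caudalmiddlefrontal",
                      "parsopercularis"),
    frontal_nonmotor = c("superiorfrontal", "rostralmiddlefrontal",
                         "parstriangularis", "parsorbitalis",
                         "lateralorbitofrontal", "medialorbitofrontal",
                         "frontalpole"),
    parietal = c("postcentral", "supramarginal", "superiorparietal",
                 "inferiorparietal", "precuneus"),
    temporal = c("superiortemporal", "middletemporal", "inferiortemporal",
                 "bankssts", "fusiform", "transversetemporal", "temporalpole"),
    occipital = c("lateraloccipital", "lingual", "cuneus", "pericalcarine"),
    limbic = c("caudalanteriorcingulate", "rostralanteriorcingulate",
               "posteriorcingulate", "isthmuscingulate", "parahippocampal",
               "entorhinal", "insula"))
}

#' Thalamic nuclei and the motor-thalamus subset
#'
#' Nucleus labels follow the probabilistic thalamic-nucleus segmentation
#' nomenclature. The motor thalamus comprises the ventral motor-relay nuclei
#' (ventral anterior and ventral lateral groups plus ventromedial); all
#' remaining nuclei form the non-motor thalamus.
#'
#' @return character vector of nucleus labels.
#' @export
thalamic_nuclei <- function() c(motor_nuclei(), nonmotor_nuclei())

#' @rdname thalamic_nuclei
#' @export
motor_nuclei <- function() c("VA", "VAmc", "VLa", "VLp", "VM")

#' @rdname thalamic_nuclei
#' @export
nonmotor_nuclei <- function() {
  c("AV", "LD", "LP", "VPL", "CM", "CeM", "MDm", "MDl",
    "LGN", "MGN", "PuA", "PuM", "PuL", "PuI")
}

subcortical_structures <- function() {
  c("hippocampus", "amygdala", "caudate", "putamen", "pallidum",
    "accumbens", "ventraldc", "cerebellum.cortex")
}

cc_segments <- function() {
  paste0("cc.", c("anterior", "mid.anterior", "central",
                  "mid.posterior", "posterior"))
}

#' Default composite region map
#'
#' Builds the per-hemisphere composites used by the analysis: motor and
#' non-motor thalamus (nucleus volume sums), subcortical grey (basal ganglia,
#' hippocampus, amygdala, ventral diencephalon, cerebellar cortex), cerebral
#' white matter, six cortical-thickness composites from the
#' Desikan-Killiany lobar assignment, and a bilateral corpus-callosum
#' composite. Region names are `lh.`/`rh.`-prefixed; thalamic nuclei carry a
#' `thal.` infix (e.g. `lh.thal.VLp`).
#'
#' @return a [region_map()] with 21 composites.
#' @export
default_region_map <- function() {
  comps <- list()
  for (h in c("lh", "rh")) {
    H <- if (h == "lh") "L" else "R"
    pre <- function(x) paste0(h, ".", x)
    comps <- c(comps, list(
      list(name = paste0("motor_thalamus_", H), hemisphere = H,
           members = pre(paste0("thal.", motor_nuclei())),
           aggregation = "sum", measure_class = "subcortical_volume"),
      list(name = paste0("nonmotor_thalamus_", H), hemisphere = H,
           members = pre(paste0("thal.", nonmotor_nuclei())),
           aggregation = "sum", measure_class = "subcortical_volume"),
      list(name = paste0("subcortical_grey_", H), hemisphere = H,
           members = pre(subcortical_structures()),
           aggregation = "sum", measure_class = "subcortical_volume"),
      list(name = paste0("white_matter_", H), hemisphere = H,
           members = pre("cerebral.wm"),
           aggregation = "sum", measure_class = "white_matter_volume")))
    for (lobe in names(dk_lobe_assignment())) {
      comps <- c(comps, list(
        list(name = paste0(lobe, "_", H), hemisphere = H,
             members = pre(dk_lobe_assignment()[[lobe]]),
             aggregation = "mean", measure_class = "cortical_thickness")))
    }
  }
  comps <- c(comps, list(
    list(name = "corpus_callosum", hemisphere = "bilateral",
         members = cc_segments(),
         aggregation = "sum", measure_class = "white_matter_volume")))
  region_map(comps)
}
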