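#' Build the canonical Sharp-van der Heijde joint-area registry
#'
#' Enumerates every location scored by the SvH method: per side, 15
#' hand/wrist and 6 foot areas for joint space narrowing (each 0-4), and 16
#' hand/wrist areas (each 0-5) plus 6 foot joints (each 0-10, the two sides
#' of the joint scored together) for erosion. Over both sides that is 42
#' JSN areas and 44 erosion locations, and the per-location caps sum to the
#' scheme's 448-point maximum.
#'
#' The anatomical names are configuration, not logic: only the
#' cardinalities and caps enter the evaluation metrics. The enumeration
#' used here is the standard one — hand JSN over MCP1-5, PIP2-5, CMC3-5 and
#' three wrist articulations; hand erosion over the thumb IP, PIP2-5,
#' MCP1-5 and six wrist bones; foot MTP1-5 plus the great-toe IP for both
#' damage types.
#'
#' Column/area identifiers follow the template
#' `{LH|RH|LF|RF}_{name}__{J|E}` (side-region prefix, anatomical name,
#' damage-type suffix).
#'
#' @return A [JointAreaRegistry-class] object.
#' @examples
#' reg <- svhRegistry()
#' maxTotalScore(reg)            # 448
#' maxTotalScore(reg, "jsn")     # 168
#' @export
svhRegistry <- function() {
  hand_jsn <- c(paste0("mcp", 1:5), paste0("pip", 2:5), paste0("cmc", 3:5),
                "capitate_scaphoid", "radiocarpal", "multangular_navicular")
  hand_ero <- c("ip1", paste0("pip", 2:5), paste0("mcp", 1:5),
                "mc1", "multangular", "scaphoid", "lunate", "radius", "ulna")
  foot <- c(paste0("mtp", 1:5), "ip1")

  one_side <- function(side) {
    rbind(
      data.frame(region = "hand_wrist", side = side, name = hand_jsn,
                 damage_type = "jsn", max_score = 4L),
      data.frame(region = "foot", side = side, name = foot,
                 damage_type = "jsn", max_score = 4L),
      data.frame(region = "hand_wrist", side = side, name = hand_ero,
                 damage_type = "erosion", max_score = 5L),
      data.frame(region = "foot", side = side, name = foot,
                 damage_type = "erosion", max_score = 10L)
    )
  }
  areas <- rbind(one_side("left"), one_side("right"))
  prefix <- ifelse(areas$region == "hand_wrist",
                   ifelse(areas$side == "left", "LH", "RH"),
                   ifelse(areas$side == "left", "LF", "RF"))
  suffix <- ifelse(areas$damage_type == "jsn", "J", "E")
  areas$area_id <- paste0(prefix, "_", areas$name, "__", suffix)
  areas <- areas[c("area_id", "region", "side", "name", "damage_type", "max_score")]
  rownames(areas) <- NULL
  new("JointAreaRegistry", areas = areas)
}

#' @rdname jointAreas
#' @export
setGeneric("jointAreas", function(x, damage_type = c("all", "jsn", "erosion"))
  standardGeneric("jointAreas"))

#' Joint areas of a registry
#'
#' @param x a [JointAreaRegistry-class].
#' @param damage_type restrict to one damage type ("all" keeps everything).
#' @return data.frame of joint areas (registry order).
#' @rdname jointAreas
#' @export
setMethod("jointAreas", "JointAreaRegistry", function(x, damage_type = c("all", "jsn", "erosion")) {
  damage_type <- match.arg(damage_type)
  a <- x@areas
  if (damage_type != "all") a <- a[a$damage_type == damage_type, ]
  a
})

#' Maximum attainable total under the SvH scheme
#'
#' Sums the per-location caps over the registry, optionally restricted to
#' one damage type. The canonical registry gives 168 for JSN, 280 for
#' erosion and 448 overall.
#'
#' @param registry a [JointAreaRegistry-class].
#' @param damage_type "overall", "jsn" or "erosion".
#' @return integer score cap.
#' @export
maxTotalScore <- function(registry, damage_type = c("overall", "jsn", "erosion")) {
  stopifnot(is(registry, "JointAreaRegistry"))
  damage_type <- match.arg(damage_type)
  a <- registry@areas
  if (damage_type != "overall") a <- a[a$damage_type == damage_type, ]
  sum(a$max_score)
}

#' Number of individual joint scores in a cohort
#'
#' n_patients times the number of registry locations of the given damage
#' type: the denominator used when reporting per-joint outlier rates (a
#' 188-patient cohort has 7896 JSN and 8272 erosion scores).
#'
#' @param n_patients positive integer.
#' @param damage_type "jsn" or "erosion".
#' @param registry a [JointAreaRegistry-class].
#' @return integer count.
#' @export
countJointScores <- function(n_patients, damage_type = c("jsn", "erosion"),
                             registry = svhRegistry()) {
  damage_type <- match.arg(damage_type)
  if (length(n_patients) != 1L || !is.finite(n_patients) ||
      n_patients < 1 || n_patients != as.integer(n_patients)) {
    stop("n_patients must be a positive integer")
  }
  as.integer(n_patients) * nrow(jointAreas(registry, damage_type))
}
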