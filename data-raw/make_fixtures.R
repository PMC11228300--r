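# Builds inst/extdata fixtures: the synthetic 196-region catalogue and
# the functional-network definition YAML. Run from the repo root:
#   Rscript data-raw/make_fixtures.R

divs <- list(
  isocortex = c("FRP", "MOp", "MOs", "SSp", "SSs", "GU", "VISC", "AUDd",
                "AUDp", "AUDv", "VISal", "VISam", "VISl", "VISp", "VISpl",
                "VISpm", "ACA", "PL", "ILA", "ORBl", "ORBm", "ORBvl", "AI",
                "RSPagl", "RSPd", "RSPv", "PTLp", "TEa", "PERI", "ECT"),
  `cortical plate` = c("MOB", "AOB", "AON", "TT", "DP", "PIR", "NLOT",
                       "COAa", "COApl", "COApm", "PAA", "TR", "HPF",
                       "ENTl", "ENTm", "PAR", "POST", "PRE", "SUB",
                       "ProS"),
  `cortical subplate` = c("CLA", "EPd", "EPv", "LA", "BLA", "BMA", "PA"),
  striatum = c("CP", "STRd", "STRv", "ACB", "FS", "OT", "LSr", "LSc",
               "SF", "AAA", "BA", "CEA", "IA", "MEA"),
  pallidum = c("GPe", "GPi", "SI", "MA", "MS", "NDB", "BST", "BAC"),
  thalamus = c("VAL", "VM", "VPL", "VPM", "SPF", "SPA", "PP", "MG",
               "LGd", "LP", "PO", "POL", "SGN", "AV", "AM", "AD", "IAM",
               "LD", "IMD", "MD", "MED", "LAT", "SMT", "PVT", "PT", "RE",
               "RH", "CM", "CL", "RT"),
  hypothalamus = c("SO", "PVH", "PVa", "ARH", "ADP", "AVP", "AVPV",
                   "DMH", "MEPO", "MPO", "PS", "SCH", "SFO", "VLPO",
                   "AHN", "MM", "SUM", "TM", "MPN", "PMv", "VMH", "PH",
                   "LHA", "LPO", "ZI"),
  midbrain = c("SCs", "SCm", "IC", "NB", "SAG", "PBG", "MEV", "SNr",
               "VTA", "RR", "MRN", "PAG", "APN", "MPT", "NOT", "NPC",
               "PPT", "CUN", "RN", "III", "EW", "SNc", "PPN", "IPN",
               "DR"),
  pons = c("NLL", "PSV", "PB", "SOC", "DTN", "PCG", "PG", "PRNc", "SG",
           "TRN", "V", "CS", "LC", "LDT", "PRNr"),
  medulla = c("AP", "DCO", "VCO", "CU", "GR", "ECU", "NTB", "NTS",
              "SPVC", "SPVI", "SPVO", "VI", "VII", "AMB", "DMX", "GRN",
              "IO", "IRN", "LRN", "MARN", "MDRN", "PARN"))

names_map <- c(
  FRP = "frontal pole", MOp = "primary motor area",
  MOs = "secondary motor area", SSp = "primary somatosensory area",
  SSs = "supplemental somatosensory area", GU = "gustatory areas",
  VISC = "visceral area", AUDd = "dorsal auditory area",
  AUDp = "primary auditory area", AUDv = "ventral auditory area",
  VISal = "anterolateral visual area", VISam = "anteromedial visual area",
  VISl = "lateral visual area", VISp = "primary visual area",
  VISpl = "posterolateral visual area", VISpm = "posteromedial visual area",
  ACA = "anterior cingulate area", PL = "prelimbic area",
  ILA = "infralimbic area", ORBl = "orbital area lateral part",
  ORBm = "orbital area medial part", ORBvl = "orbital area ventrolateral part",
  AI = "agranular insular area", RSPagl = "retrosplenial area lateral agranular part",
  RSPd = "retrosplenial area dorsal part", RSPv = "retrosplenial area ventral part",
  PTLp = "posterior parietal association areas", TEa = "temporal association areas",
  PERI = "perirhinal area", ECT = "ectorhinal area",
  MOB = "main olfactory bulb", AOB = "accessory olfactory bulb",
  AON = "anterior olfactory nucleus", TT = "taenia tecta",
  DP = "dorsal peduncular area", PIR = "piriform area",
  NLOT = "nucleus of the lateral olfactory tract",
  COAa = "cortical amygdalar area anterior part",
  COApl = "cortical amygdalar area posterior lateral zone",
  COApm = "cortical amygdalar area posterior medial zone",
  PAA = "piriform-amygdalar area", TR = "postpiriform transition area",
  HPF = "hippocampal formation", ENTl = "entorhinal area lateral part",
  ENTm = "entorhinal area medial part", PAR = "parasubiculum",
  POST = "postsubiculum", PRE = "presubiculum", SUB = "subiculum",
  ProS = "prosubiculum",
  CLA = "claustrum", EPd = "endopiriform nucleus dorsal part",
  EPv = "endopiriform nucleus ventral part", LA = "lateral amygdalar nucleus",
  BLA = "basolateral amygdalar nucleus", BMA = "basomedial amygdalar nucleus",
  PA = "posterior amygdalar nucleus",
  CP = "caudoputamen", STRd = "striatum dorsal region",
  STRv = "striatum ventral region", ACB = "nucleus accumbens",
  FS = "fundus of striatum", OT = "olfactory tubercle",
  LSr = "lateral septal nucleus rostral part",
  LSc = "lateral septal nucleus caudal part", SF = "septofimbrial nucleus",
  AAA = "anterior amygdalar area", BA = "bed nucleus of the accessory olfactory tract",
  CEA = "central amygdalar nucleus", IA = "intercalated amygdalar nucleus",
  MEA = "medial amygdalar nucleus",
  GPe = "globus pallidus external segment",
  GPi = "globus pallidus internal segment", SI = "substantia innominata",
  MA = "magnocellular nucleus", MS = "medial septal nucleus",
  NDB = "diagonal band nucleus", BST = "bed nuclei of the stria terminalis",
  BAC = "bed nucleus of the anterior commissure",
  VAL = "ventral anterior-lateral complex", VM = "ventral medial nucleus",
  VPL = "ventral posterolateral nucleus", VPM = "ventral posteromedial nucleus of the thalamus",
  SPF = "subparafascicular nucleus", SPA = "subparafascicular area",
  PP = "peripeduncular nucleus", MG = "medial geniculate complex",
  LGd = "dorsal part of the lateral geniculate complex",
  LP = "lateral posterior nucleus", PO = "posterior complex",
  POL = "posterior limiting nucleus", SGN = "suprageniculate nucleus",
  AV = "anteroventral nucleus", AM = "anteromedial nucleus",
  AD = "anterodorsal nucleus", IAM = "interanteromedial nucleus",
  LD = "lateral dorsal nucleus", IMD = "intermediodorsal nucleus",
  MD = "mediodorsal nucleus of thalamus",
  MED = "medial group of dorsal thalamus",
  LAT = "lateral group of the dorsal thalamus",
  SMT = "submedial nucleus", PVT = "paraventricular nucleus of the thalamus",
  PT = "parataenial nucleus", RE = "nucleus of reuniens",
  RH = "rhomboid nucleus", CM = "central medial nucleus",
  CL = "central lateral nucleus", RT = "reticular nucleus of the thalamus",
  SO = "supraoptic nucleus", PVH = "paraventricular hypothalamic nucleus",
  PVa = "periventricular hypothalamic nucleus anterior part",
  ARH = "arcuate hypothalamic nucleus", ADP = "anterodorsal preoptic nucleus",
  AVP = "anteroventral preoptic nucleus",
  AVPV = "anteroventral periventricular nucleus",
  DMH = "dorsomedial nucleus of the hypothalamus",
  MEPO = "median preoptic nucleus", MPO = "medial preoptic area",
  PS = "parastrial nucleus", SCH = "suprachiasmatic nucleus",
  SFO = "subfornical organ", VLPO = "ventrolateral preoptic nucleus",
  AHN = "anterior hypothalamic nucleus", MM = "medial mammillary nucleus",
  SUM = "supramammillary nucleus", TM = "tuberomammillary nucleus",
  MPN = "medial preoptic nucleus", PMv = "ventral premammillary nucleus",
  VMH = "ventromedial hypothalamic nucleus", PH = "posterior hypothalamic nucleus",
  LHA = "lateral hypothalamic area", LPO = "lateral preoptic area",
  ZI = "zona incerta",
  SCs = "superior colliculus sensory related",
  SCm = "superior colliculus motor related", IC = "inferior colliculus",
  NB = "nucleus of the brachium of the inferior colliculus",
  SAG = "nucleus sagulum", PBG = "parabigeminal nucleus",
  MEV = "midbrain trigeminal nucleus", SNr = "substantia nigra reticular part",
  VTA = "ventral tegmental area", RR = "midbrain reticular nucleus retrorubral area",
  MRN = "midbrain reticular nucleus", PAG = "periaqueductal gray",
  APN = "anterior pretectal nucleus", MPT = "medial pretectal area",
  NOT = "nucleus of the optic tract", NPC = "nucleus of the posterior commissure",
  PPT = "posterior pretectal nucleus", CUN = "cuneiform nucleus",
  RN = "red nucleus", III = "oculomotor nucleus",
  EW = "Edinger-Westphal nucleus", SNc = "substantia nigra compact part",
  PPN = "pedunculopontine nucleus", IPN = "interpeduncular nucleus",
  DR = "dorsal nucleus raphe",
  NLL = "nucleus of the lateral lemniscus",
  PSV = "principal sensory nucleus of the trigeminal",
  PB = "parabrachial nucleus", SOC = "superior olivary complex",
  DTN = "dorsal tegmental nucleus", PCG = "pontine central gray",
  PG = "pontine gray", PRNc = "pontine reticular nucleus caudal part",
  SG = "supragenual nucleus", TRN = "tegmental reticular nucleus",
  V = "motor nucleus of trigeminal", CS = "superior central nucleus raphe",
  LC = "locus ceruleus", LDT = "laterodorsal tegmental nucleus",
  PRNr = "pontine reticular nucleus",
  AP = "area postrema", DCO = "dorsal cochlear nucleus",
  VCO = "ventral cochlear nucleus", CU = "cuneate nucleus",
  GR = "gracile nucleus", ECU = "external cuneate nucleus",
  NTB = "nucleus of the trapezoid body",
  NTS = "nucleus of the solitary tract",
  SPVC = "spinal nucleus of the trigeminal caudal part",
  SPVI = "spinal nucleus of the trigeminal interpolar part",
  SPVO = "spinal nucleus of the trigeminal oral part",
  VI = "abducens nucleus", VII = "facial motor nucleus",
  AMB = "nucleus ambiguus", DMX = "dorsal motor nucleus of the vagus nerve",
  GRN = "gigantocellular reticular nucleus", IO = "inferior olivary complex",
  IRN = "intermediate reticular nucleus", LRN = "lateral reticular nucleus",
  MARN = "magnocellular reticular nucleus",
  MDRN = "medullary reticular nucleus",
  PARN = "parvicellular reticular nucleus")

acr <- unlist(divs, use.names = FALSE)
division <- rep(names(divs), lengths(divs))
stopifnot(length(acr) == 196, !anyDuplicated(acr),
          all(acr %in% names(names_map)))

required <- c("AI", "BLA", "CEA", "MEA", "MED", "DR", "CLA", "HPF",
              "ACA", "PL", "VTA", "MD", "ACB", "MPO", "STRd", "VISp",
              "BMA", "LAT", "ZI", "CS", "MOp", "SSp", "VPM")
stopifnot(all(required %in% acr))

set.seed(196)
vol <- round(pmax(rlnorm(196, meanlog = log(0.8), sdlog = 0.9), 0.02), 4)

tab <- data.frame(acronym = acr, name = unname(names_map[acr]),
                  division = division, volume_mm3 = vol)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "inst/extdata/synthetic_regions_196.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

nets <- list(
  salience = c("AI", "BLA", "CEA", "MEA", "MED", "DR", "CLA"),
  social = c("HPF", "ACA", "PL", "VTA", "MD", "ACB", "MPO", "MEA",
             "CEA", "BLA"),
  default_mode = c("STRd", "VISp", "BMA", "LAT", "ZI", "CS", "ACA",
                   "PL", "HPF", "MEA"),
  lateral_cortical = c("MOp", "SSp", "VPM", "ACA"))
yaml::write_yaml(nets, "inst/extdata/functional_networks.yaml")
cat("wrote fixtures:", nrow(tab), "regions;",
    length(nets), "networks\n")
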