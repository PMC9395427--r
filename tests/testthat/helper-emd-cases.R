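emd_oracle_cases <- list(
  list(H = 1L, W = 4L,
       P = matrix(c(0.210088019698712, 0.411004780306645, 0.333825166506348, 0.045082033488296), 1, 4),
       Q = matrix(c(0.368028833068912, 0.287120683383261, 0.296522858975983, 0.048327624571844), 1, 4),
       emd = 0.048810780225),
  list(H = 4L, W = 2L,
       P = matrix(c(0.091481775897391, 0.158851775829367, 0.109397342261455, 0.136824896267683, 0.228647677384108, 0.202988388835121, 0.056063410436311, 0.015744733088563), 4, 2),
       Q = matrix(c(0.153017069673400, 0.140159491895303, 0.179468067730052, 0.143911884707779, 0.116785639112604, 0.065546739419868, 0.165125216972094, 0.035985890488900), 4, 2),
       emd = 0.114012304615),
  list(H = 2L, W = 2L,
       P = matrix(c(0.026941169896675, 0.420104015404452, 0.094894567724025, 0.458060246974848), 2, 2),
       Q = matrix(c(0.453516514753422, 0.173651581069688, 0.152729399909316, 0.220102504267574), 2, 2),
       emd = 0.279509764737),
  list(H = 4L, W = 1L,
       P = matrix(c(0.086478866287964, 0.316640594652858, 0.151036298458765, 0.445844240600412), 4, 1),
       Q = matrix(c(0.191526494639940, 0.364815820700176, 0.306802542811987, 0.136855141847898), 4, 1),
       emd = 0.141814895376),
  list(H = 4L, W = 4L,
       P = matrix(c(0.108779194550822, 0.018890203650151, 0.089867226353639, 0.076876179501865, 0.052375065550698, 0.027021392096669, 0.095316500038216, 0.018896220633143, 0.038973021878671, 0.000995150650150, 0.105530363473324, 0.015480915668086, 0.092252235720132, 0.106367782270266, 0.062031187098051, 0.090347360866116), 4, 4),
       Q = matrix(c(0.070692096551317, 0.083069419642589, 0.065533255081816, 0.035104661226955, 0.084818610068617, 0.083913914151947, 0.032200302637933, 0.008748835144382, 0.114794753990590, 0.045610364504817, 0.061303287841351, 0.042224108374078, 0.095245022514019, 0.004624484995571, 0.128060578000780, 0.044056305273239), 4, 4),
       emd = 0.111368359427),
  list(H = 2L, W = 3L,
       P = matrix(c(0.164189176640582, 0.119785408969562, 0.231059555507225, 0.239938280340198, 0.195811126447720, 0.049216452094714), 2, 3),
       Q = matrix(c(0.011591855071266, 0.235734267067405, 0.045958893555719, 0.082310367645642, 0.368679902188422, 0.255724714471545), 2, 3),
       emd = 0.206030826908),
  list(H = 4L, W = 1L,
       P = matrix(c(0.381543327483050, 0.244467857113841, 0.208777613939983, 0.165211201463125), 4, 1),
       Q = matrix(c(0.526221710444026, 0.302076644451626, 0.073178747067348, 0.098522898037000), 4, 1),
       emd = 0.103413464171),
  list(H = 2L, W = 4L,
       P = matrix(c(0.179540881135642, 0.153885752705471, 0.138266239450278, 0.141661712113717, 0.052537466001798, 0.088796472199402, 0.191514944731373, 0.053796531662319), 2, 4),
       Q = matrix(c(0.026957256652139, 0.085565607577576, 0.252427031693294, 0.161987910786109, 0.127465045959794, 0.049437303792208, 0.056594114633781, 0.239565728905099), 2, 4),
       emd = 0.157002643912)
)
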