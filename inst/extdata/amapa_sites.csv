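name,lat,lon,order
OIA,03°49′53″ N,51°50′07″ W,6
CAL,02°29′53″ N,50°56′59″ W,5
TTZ,01°30′21″ N,50°54′41″ W,4
FGO,00°51′14″ N,51°11′39″ W,3
PGR,00°42′16″ N,51°24′35″ W,2
MAC,00°02′04″ N,51°03′60″ W,1
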