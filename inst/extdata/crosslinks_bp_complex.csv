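Protein1,Residue1,Protein2,Residue2,Peptide,Annotation
EcDnaB,373,EcDnaB,175,ALAKELNVPVVALSQLNR(4)-ANKDEGPK(3):0,Yes
EcDnaB,167,EcDnaB,175,VFKIAESR(3)-ANKDEGPK(3):0,Yes
EcDnaB,217,EcDnaB,283,KTAGLQPSDLIIVAAR(1)-VDQTKIR(5):0,Yes
EcDnaB,307,EcDnaB,283,ISGTMGILLEKR(11)-VDQTKIR(5):0,Yes
EcDnaB,373,EcDnaB,167,ALAKELNVPVVALSQLNR(4)-VFKIAESR(3):0,Yes
EcDnaB,373,EcDnaB,2,ALAKELNVPVVALSQLNR(4)-AGNKPFNK(1):0,DnaB residue two is not observed in our map
EcDnaB,180,EcDnaB,167,ANKDEGPKNIADVLDATVAR(8)-VFKIAESR(3):0,Yes
EcDnaB,180,EcDnaB,373,ANKDEGPKNIADVLDATVAR(8)-ALAKELNVPVVALSQLNR(4):0,Yes
lambdaP,177,EcDnaB,395,KAADELVHMTAR(1)-ADKRPVNSDLR(3):0,Yes
lambdaP,200,EcDnaB,283,GEAIPEPVKQLPVMGGR(9)-VDQTKIR(5):0,Yes
lambdaP,200,EcDnaB,217,INRGEAIPEPVKQLPVMGGR(12)-KTAGLQPSDLIIVAAR(1):0,Yes
EcDnaB,175,lambdaP,229,ANKDEGPK(3)-FGLKGASV(4):0,Yes
EcDnaB,2,lambdaP,229,AGNKPFNK(1)-FGLKGASV(4):0,DnaB residue two is not observed in our map
EcDnaB,167,lambdaP,229,VFKIAESR(3)-FGLKGASV(4):0,Yes
EcDnaB,373,lambdaP,200,ALAKELNVPVVALSQLNR(4)-GEAIPEPVKQLPVMGGR(9):0,No
EcDnaB,373,lambdaP,229,ALAKELNVPVVALSQLNR(4)-FGLKGASV(4):0,Yes
lambdaP,218,lambdaP,225,AQALAKIAEIK(6)-AKFGLK(2):0,Yes
lambdaP,229,lambdaP,223,FGLKGASV(4)-IAEIKAK(5):0,Yes
lambdaP,200,lambdaP,177,GEAIPEPVKQLPVMGGR(9)-KAADELVHMTAR(1):0,Yes
lambdaP,30,lambdaP,2,IANNMPEQYDEKPQVQQVAQIINGVFSQLLATFPASLANR(12)-MKNIAAQMVNFDR(2):0,Lambda P residues 2 and 30 are not observed in our map
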