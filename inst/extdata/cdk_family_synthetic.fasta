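>CDK4_mammal_01|CDK4|mammal
TCAIMWTPEDCFVWPNHDCMCVRGNAILPGDNWMCDRWNTWHQRVNRQIGCATEDMIHKV
HLNSCFCPATWCFGGDDEPWMWRTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFACNMLVTVDVLTHTMTVATARGSNCMKAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFSTLWQIDVPETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVLAFADMFPPRGPRPVQSVVLHIEYWKIHYPFNVIRTWYITICMWYYISRDMAFVYKYQ
>CDK4_mammal_02|CDK4|mammal
TCAIDWTPEDCFAWPNHCYMCCRGNANLPGDDWICDRWNTWQQRVNRQIECATEDMIHKV
HLNSCFPRWTWCFGGDDEIWMYSTKHLSGQAMFCHILLIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRHCITTCNFFAGNMLVTVDVLTHTMTVETARGSNCMKAYCPQSIEHGNWPP
VSAQLHVMCLPRQQFSTLWVIDVPETCVWHLQIHYKLYDITWQPHIEEFKYICRNRFSDQ
VVLLFADMFPPRGPRPVQSVVLHIMYDKIHYPFNVIRNWYFTIAMWYYISRTEAFCYVYQ
>CDK4_mammal_03|CDK4|mammal
VCAIDFTPEDCFVWPNHDVMCVRGNAILPSDDWMCDRWNTWQQRVNRQIGTATEDMIHKV
HLNSCFCRWTWCNGRDDEIWMYSTKQLSGQAMFCHSLIIAYTFFPQPLCETTWRQQQVPR
IKHARRLFRRICITTCNFIACNMLVTMDVLTHTMTVATARGSNCMKAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFSTLWRIDVPETCVWLLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVLAFADMFPPRGPRPVQSVILHNEYWKIHYPFNVIRTWYFTICMWYYISRDEAFVYKYQ
>CDK4_mammal_04|CDK4|mammal
TCAIWWTPEDCFVWPNHDCMCVRGNAILPGDDWICNRWNTWQQRVNRQIWCATEDDIHLV
HLNSCFCRWTWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFGCNMLITVDVLTHTMTVATARGSNCMKAYCPQSIEHTNWPP
ESAQLHVNCLYRQAFSTLLRIQVPETCVWHLQIHYTLYDITKQPFIWEFKYICRNRFSDQ
VVLADADMFPPRGPRPVQSVVLHIEYWKIHYPFNVIRTWYFTICMWYYISRDVAFVYKYQ
>CDK4_mammal_05|CDK4|mammal
TCAIDWTPEDCFVWPNHDCMCVRGNAILKGDDWMCDRWNTWQQTVNRQIGCATEDMIHKV
HLNSCFCRWTWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFDPQPLCSTMWRQQQVPR
IKHARQLFRRICDTTCNFFACNMLVTVDVLTHTMTVATARGSNCMKAACPQSIEHHNWPP
VSAQLHVMCLPFQAFSTLWRIDVPETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVLAFADHFPPRGPRPVQSVVLHIEYWKIHYPFNVIRTWHFTICMWMYISRDEAFVYKYQ
>CDK4_mammal_06|CDK4|mammal
TCAIDWTPEDCPVWWNHDCMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGCATFDMIHKG
HLNSCFCRWTWCFGGDDEITMYSTKHLSGQAMFCHSLIIARTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICCTTCNFFACNMLVTVDVLTHTMTVATARGSNCMKAYCPQSDEHHHWPP
VSAQLHVMCLPRGAFSTLGRIDVPETCVWHLQIHYSLYDITKQPHIWEFKYICRNRFSDQ
VVLKFADMFPPRGPRPVQSVVLHIEYWKIKYPFNVIRTWYFTICMWWYISRDEAFVYKYQ
>CDK4_mammal_07|CDK4|mammal
TCAIDWTPEDCFVWPNHDCMCVRGNDILPGDDWMCDRWNTWQQRVNRDIGCATEDMIHKV
HCNSCFCRDTWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFFPQPLESTTWRQQQVPR
IKHARRLFRRICITFCNFFACNMLVTVDVLTHFMTVATARGENCMKAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFSTLWRIDVPETRVWHTQIHYHDYDITKQPHIWEFKYWPRNRFSDF
VVLAFADMFPPRGPRPVQSVVLHIEYWKIVYPFNCIRTWYFTICMWYYISRDEAFVYKYQ
>CDK4_mammal_08|CDK4|mammal
TCAIDWTPEDCFVWPNHDCMCVRGNAILPGDDWMCDRWVTWQQRVNRQIGCATEDMIHKK
HLNSCFCRWTWCFGGDDEAWMYSTKHLSGQAMFCHSLIHAYTWFPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFACVMLVTVYVLTHTMTVATARGSNCMKAYCPQSIEHHNWPP
VSAQLDVMCLKRQAFSTLWRIDVPETCVWHLQIHYHLYDITKQPHIVEFKYICRNRFSDQ
VVLAFADHFPPRGPRPVQSVVLHIEKWKIHYPFNIIRTYYFTICMWYYISRDEAFVYKYQ
>CDK4_nonmammal_01|CDK4|nonmammal
TCAIDWGPEDCFVWPNHDCMCVRGNAIVPGDDWMCDRNNTWQQMWNRHIGCATEDMIRKV
HSNSCFCRWTWCTMGDDEIWMYSTKHFSGQAMFCHSSIIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFACNMLVTVDVLTHTMTVATARGSNCMKAYCPQSIEHHNIPP
VSAQLHDMCLPRQAFSTLWQIDVPETCVWHLQIHYHLYDITSQPHIWEFKYILRNRFSDQ
VVLAFADSEYPGNKEFVDPMVLHIEYWKIHYPFNVIRLWYFTICMWYYISRDEAFVYKYQ
>CDK4_nonmammal_02|CDK4|nonmammal
TCAIDWTPEDCFVWPNHDCMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGCATEDMIHKV
RLESCFCRWTWCFGGDDEIWMYSTKHLSGQAMFCHSLCIAWTFEPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFACNPLVTVDVLTHTMTVATARGSNCMKAYCPQSIEHHNWPP
DMAQAHVMCLPRQAGSTLWRIDVPETCVWHLQIHYHLYDITKQPHIWEFVYICRNRFSDQ
VVLAFGDMFVMVTLFHCQNFVLHIEYWKIHYPFNVIRTWYFTICMWYYISRDEAFVYKYQ
>CDK4_nonmammal_03|CDK4|nonmammal
TCAIDWTPEDCFVWPNHDCMCVRMNAILPGDDWMCDRWNTWQQRVNRQIGCATEIMIHKV
HLNSCTCRWTWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQRQVPR
IKHARRLFRRICITTCNFFACNMLVTVDVLTHTMTVATARGMNCMFAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFSTLWRIDVVETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVLAFAQMHVHNRGMIDNGFVMHIEDWKIHYAFNVIRTWYFTICMWYYISRDEAFVYKYQ
>CDK4_nonmammal_04|CDK4|nonmammal
TCAIDWTPEDCFVWPNHDCMTVVGNAILPGDDWMCDRWNTWQQRVNRQIGCATEDMIHKV
HLNSCFCRWTWCFGGDDEIWMYSTKYLSGQAMFCHSLLIAYTFFPQPLCSTTWRQQQVPR
IKHARNLFRMICITTCNFFACNMLVTVVVLTYTMTVATARGSNCMKAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFSLLWRIDVPETCVWHLQIHYHLVDITKQPHIWEFKYICRNRFWDC
VVLAFAEMFCKSYYMYAQVGVLHIEYWKIHYPFNVIRTWYFTICMWYYISRDEAFVYKYQ
>CDK6_mammal_01|CDK6|mammal
LCAIDWTPEDCFVWPNHDCMCVRSNAILPGDDWMCDRWNTRQQRVNRQIGCATEDMIHKV
MLNSCFCRWTWCFPGDDEIWMYPTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPR
IKHRRRLFRRICITTCNFFACNMLVTVDVNTYCMCVATARGGNCMKAYCPQSIEHHNWIP
VSAQLHVMCLPRQLFSTLWRIDVPETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVDAFADMSAKCHPQMLELSVLHIEYWKIHYPFNVIRTWYFRICMWYYISRDEAFDYKYQ
>CDK6_mammal_02|CDK6|mammal
TCAIDWTPEDCFGWPNHDCMCVRGNAILPGDDWMCDRWNTWQQRENRQIGCATEDVIHKV
HLNSCFCRWTWCFGGDDEIWKYSTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICITTCNFFACNMLVTVYVLTHTMWVATARGSNCMKAYCPQSIEHHNWPP
VSAQLHVMCLPRQAFWTLWRIDVPETCDWHLQIHYWLYDITKQPHIWAFKYICRNRFSDL
AVLAFADMLPATWSMGQQYCVLHIEYWKIHYPFNVIRTWYFTICMWYYISRDEAFVYKYQ
>CDK2_mammal_01|CDK2|mammal
TCAISWTPEDPFVWPNHDCMCVKGNAIPPGDDWMYDRWNTWQQRVNNQIGCATEDMIHKV
HLNSCFCRWTWCFGGDSEPWMYWTKHLSGQAMFCHSLIIAYTFFPQPLCSTTWRQQQVPR
IKHARRLFRRICIDTCNFFACNMLVYVDVLTHTMTVATARGSNCMKAYCPQSIEHGNWPP
VDAQLHVMCLPRQAFSTLWRIDVPETHVWHLQIHYHLYDITKQPHIWEFKPICRNRFSDQ
VVLAFADMGPMGLPMMRAILVLHIEYWKIHYPFNVIRTTYHTICMWEYISRDEAYVYKYQ
>CDK2_mammal_02|CDK2|mammal
TGAIDWTPEDCFVWPNHDGMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGSATEDMIHKV
HLNSCECRWCWCFGGDDEIWMYSTKHLSGQAMFCHSLIIAYTFFPCPLLSTTWRQQQVPR
IKHARRLFRRICITTHNFFACNMLVTTRVLTHTMTVATARGSNCMKAYCPQSILHHNWPP
VSHQLHVMCLPRQAFSTLWRIDIPETCVWHLQIHYHLYDITKQPHIWEFKYICRNRFSDQ
VVLAFADMQENGGGTKCGTYVLHIEYWWIHYPFNVIRTWYFTRCMWYYISRDEAFVYKYQ
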