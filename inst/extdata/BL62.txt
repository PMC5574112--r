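# BL62: raw-scale (odds-ratio) kernel matrix underlying BLOSUM62
# Entries are target/background frequency ratios q_ij/(p_i p_j), full
# double precision, as distributed with NCBI BLAST+ (matrix_freq_ratios).
# Symmetric positive definite; suitable as an amino-acid kernel K1.
A C D E F G H I K L M N P Q R S T V W Y
A 3.9029407 0.867987664 0.544605275 0.741264113 0.464893827 1.05686961 0.569364849 0.632481035 0.775390239 0.601945975 0.723150342 0.58830764 0.754121369 0.756803943 0.6126986 1.47210399 0.984401956 0.936458396 0.416548781 0.542611869
C 0.867987664 19.5765857 0.301454345 0.285934574 0.438990118 0.42038787 0.355049505 0.653458801 0.349128465 0.642275633 0.61135434 0.39780262 0.379562691 0.365781531 0.308939296 0.738415701 0.740551692 0.755844055 0.449983903 0.434203398
D 0.544605275 0.301454345 7.39792738 1.68781075 0.298969081 0.634301019 0.678558839 0.339015407 0.784090406 0.286613046 0.346454634 1.55385281 0.598716826 0.897081129 0.573200024 0.913504624 0.694789868 0.336500142 0.232102315 0.345683565
E 0.741264113 0.285934574 1.68781075 5.46952608 0.330743991 0.481267655 0.960040718 0.330522558 1.30827885 0.372873704 0.500342289 0.911298183 0.679202587 1.90173784 0.960797602 0.950357185 0.74142561 0.42894313 0.374300212 0.496467354
F 0.464893827 0.438990118 0.298969081 0.330743991 8.12879702 0.340640908 0.651990521 0.945769883 0.344043119 1.15459749 1.00437163 0.354288952 0.287444758 0.333972402 0.38072633 0.439973597 0.481693683 0.745089738 1.37437942 2.76938063
G 1.05686961 0.42038787 0.634301019 0.481267655 0.340640908 6.87630691 0.492966576 0.275009722 0.588871736 0.284504012 0.3954866 0.863711406 0.477385507 0.538649627 0.449983999 0.903596525 0.579271582 0.336954912 0.421690355 0.348714366
H 0.569364849 0.355049505 0.678558839 0.960040718 0.651990521 0.492966576 13.5059997 0.326288125 0.77888749 0.380675486 0.584132623 1.22200067 0.472879831 1.16798104 0.917048021 0.73673174 0.557503254 0.339447442 0.444088955 1.79790413
I 0.632481035 0.653458801 0.339015407 0.330522558 0.945769883 0.275009722 0.326288125 3.99792994 0.396372934 1.69443475 1.4777445 0.327934752 0.38466286 0.382937802 0.354751311 0.443163582 0.77981611 2.41751209 0.40887439 0.630388931
K 0.775390239 0.349128465 0.784090406 1.30827885 0.344043119 0.588871736 0.77888749 0.396372934 4.76433717 0.428270363 0.625302816 0.939841129 0.703774479 1.55432308 2.07680867 0.931919141 0.792905803 0.45654272 0.358930071 0.532179333
L 0.601945975 0.642275633 0.286613046 0.372873704 1.15459749 0.284504012 0.380675486 1.69443475 0.428270363 3.79662137 1.99429557 0.310043276 0.371121724 0.477325586 0.473919278 0.428893743 0.660328975 1.31423573 0.568037074 0.692059423
M 0.723150342 0.61135434 0.346454634 0.500342289 1.00437163 0.3954866 0.584132623 1.4777445 0.625302816 1.99429557 6.48145121 0.474529655 0.423898024 0.864250293 0.622623369 0.598558924 0.793801616 1.26893679 0.610296214 0.708364628
N 0.58830764 0.39780262 1.55385281 0.911298183 0.354288952 0.863711406 1.22200067 0.327934752 0.939841129 0.310043276 0.474529655 7.09409488 0.499932836 1.00058442 0.858630478 1.23152924 0.984152635 0.369033853 0.277782896 0.486030806
P 0.754121369 0.379562691 0.598716826 0.679202587 0.287444758 0.477385507 0.472879831 0.38466286 0.703774479 0.371121724 0.423898024 0.499932836 12.8375437 0.641280589 0.481534905 0.755503259 0.688897122 0.443082984 0.281833164 0.363521119
Q 0.756803943 0.365781531 0.897081129 1.90173784 0.333972402 0.538649627 1.16798104 0.382937802 1.55432308 0.477325586 0.864250293 1.00058442 0.641280589 6.24442175 1.40579606 0.965555228 0.791320741 0.466777931 0.509360272 0.611094097
R 0.6126986 0.308939296 0.573200024 0.960797602 0.38072633 0.449983999 0.917048021 0.354751311 2.07680867 0.473919278 0.622623369 0.858630478 0.481534905 1.40579606 6.66557707 0.767165633 0.677754679 0.420072316 0.395102106 0.555965425
S 1.47210399 0.738415701 0.913504624 0.950357185 0.439973597 0.903596525 0.73673174 0.443163582 0.931919141 0.428893743 0.598558924 1.23152924 0.755503259 0.965555228 0.767165633 3.84284741 1.61392097 0.565223766 0.385303035 0.557520051
T 0.984401956 0.740551692 0.694789868 0.74142561 0.481693683 0.579271582 0.557503254 0.77981611 0.792905803 0.660328975 0.793801616 0.984152635 0.688897122 0.791320741 0.677754679 1.61392097 4.83210516 0.980943005 0.430934144 0.573156574
V 0.936458396 0.755844055 0.336500142 0.42894313 0.745089738 0.336954912 0.339447442 2.41751209 0.45654272 1.31423573 1.26893679 0.369033853 0.443082984 0.466777931 0.420072316 0.565223766 0.980943005 3.6921564 0.374456332 0.658038693
W 0.416548781 0.449983903 0.232102315 0.374300212 1.37437942 0.421690355 0.444088955 0.40887439 0.358930071 0.568037074 0.610296214 0.277782896 0.281833164 0.509360272 0.395102106 0.385303035 0.430934144 0.374456332 38.1077833 2.10980812
Y 0.542611869 0.434203398 0.345683565 0.496467354 2.76938063 0.348714366 1.79790413 0.630388931 0.532179333 0.692059423 0.708364628 0.486030806 0.363521119 0.611094097 0.555965425 0.557520051 0.573156574 0.658038693 2.10980812 9.83220341
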