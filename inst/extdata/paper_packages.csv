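trade_name,atc_code,substance,form,strength_value,strength_unit,divisible,package_sizes,marketing_status,dose_prespecified,paediatric
Amoxicillin tablets 500,J01CA04,amoxicillin,tablet,500,mg,true,16;20,marketed,true,false
Amoxicillin tablets 1000 scored,J01CA04,amoxicillin,tablet,1000,mg,true,16,marketed,true,false
Amoxicillin tablets 1000 plain,J01CA04,amoxicillin,tablet,1000,mg,false,20,marketed,true,false
Co-amoxiclav tablets 1000,J01CR02,Co-amoxiclav,tablet,1000,mg,false,10;12;14;16;20;21;24;30,marketed,true,false
Azithromycin tablets 125,J01FA10,azithromycin,tablet,125,mg,false,6,marketed,true,false
Azithromycin capsules 250,J01FA10,azithromycin,capsule,250,mg,false,6,marketed,true,false
Azithromycin tablets 500,J01FA10,azithromycin,tablet,500,mg,false,1;2;3;6;12;24,marketed,true,false
Azithromycin tablets 1000,J01FA10,azithromycin,tablet,1000,mg,false,1;2;3;6,marketed,true,false
Cephalexin capsules 500,J01DB01,cephalexin,capsule,500,mg,false,16,marketed,true,false
Cephalexin tablets 1000,J01DB01,cephalexin,tablet,1000,mg,false,16,marketed,true,false
Clindamycin capsules 150,J01FF01,clindamycin,capsule,150,mg,false,16,marketed,true,false
Clindamycin capsules 300,J01FF01,clindamycin,capsule,300,mg,false,16,marketed,true,false
Clindamycin tablets 600,J01FF01,clindamycin,tablet,600,mg,true,16;32,marketed,true,false
Clarithromycin tablets 250,J01FA09,clarithromycin,tablet,250,mg,false,14,marketed,true,false
Clarithromycin tablets 500,J01FA09,clarithromycin,tablet,500,mg,false,5;7;14,marketed,true,false
Penicillin V tablets 1M,J01CE02,Penicillin V,tablet,1000000,IU,true,30,marketed,true,false
Penicillin V tablets 1.5M,J01CE02,Penicillin V,tablet,1500000,IU,true,30,marketed,true,false
Erythromycin tablets 250,J01FA01,erythromycin,tablet,250,mg,false,16,marketed,true,false
Cefixime tablets 400,J01DD08,cefixime,tablet,400,mg,false,5;10,marketed,true,false
Cefuroxime tablets 125,J01DC02,cefuroxime,tablet,125,mg,false,10,marketed,true,false
Cefuroxime tablets 250,J01DC02,cefuroxime,tablet,250,mg,false,10,marketed,true,false
Cefuroxime tablets 500,J01DC02,cefuroxime,tablet,500,mg,false,8;10;12;14;15;16;20;24,marketed,true,false
Norfloxacin tablets 400,J01MA06,norfloxacin,tablet,400,mg,false,20,marketed,true,false
Ciprofloxacin tablets 250,J01MA02,ciprofloxacin,tablet,250,mg,false,10,marketed,true,false
Ciprofloxacin tablets 500,J01MA02,ciprofloxacin,tablet,500,mg,false,10,marketed,true,false
Fosfomycinum granules 2g,J01XX01,Fosfomycinum,other-solid,2000,mg,false,1;2,marketed,true,false
Fosfomycinum granules 3g,J01XX01,Fosfomycinum,other-solid,3000,mg,false,1;2,marketed,true,false
Levofloxacin tablets 500,J01MA12,levofloxacin,tablet,500,mg,true,1;5;7;10;14,marketed,true,false
Nitrofurantoin tablets 50,J01XE01,nitrofurantoin,tablet,50,mg,false,30,marketed,true,false
Sulfametoxazole-trimethoprim tablets 120,J01EE01,sulfametoxazole/trimethoprim,tablet,120,mg,false,20,marketed,true,false
Sulfametoxazole-trimethoprim tablets 480,J01EE01,sulfametoxazole/trimethoprim,tablet,480,mg,false,20,marketed,true,false
Sulfametoxazole-trimethoprim tablets 960,J01EE01,sulfametoxazole/trimethoprim,tablet,960,mg,false,20,marketed,true,false
Linezolid tablets 600,J01XX08,linezolid,tablet,600,mg,false,10;20;28;30,marketed,true,false
Moxifloxacin tablets 400,J01MA14,moxifloxacin,tablet,400,mg,false,1;5;7;10;14;25;28;30,marketed,true,false
Telithromycin tablets 400,J01FA15,telithromycin,tablet,400,mg,false,10;14;20,marketed,true,false
Doxycycline capsules 100,J01AA02,doxycycline,capsule,100,mg,false,5;6;25,marketed,true,false
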