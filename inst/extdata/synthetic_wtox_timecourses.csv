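time_min,intensity,label,state,isomer,direction
0,6.57533593837886e-05,M8B,WT_ox,B,decay
20,5.37222229076274e-05,M8B,WT_ox,B,decay
40,4.30661370940802e-05,M8B,WT_ox,B,decay
60,3.4820746703284e-05,M8B,WT_ox,B,decay
80,2.87411972501289e-05,M8B,WT_ox,B,decay
100,2.35413865746005e-05,M8B,WT_ox,B,decay
120,1.95749069734294e-05,M8B,WT_ox,B,decay
140,1.50993925775952e-05,M8B,WT_ox,B,decay
160,1.158016536836e-05,M8B,WT_ox,B,decay
180,1.08747030900653e-05,M8B,WT_ox,B,decay
200,7.33920099170531e-06,M8B,WT_ox,B,decay
220,6.62717055372591e-06,M8B,WT_ox,B,decay
240,4.82787248268652e-06,M8B,WT_ox,B,decay
260,4.6052272381658e-06,M8B,WT_ox,B,decay
280,3.50339656377935e-06,M8B,WT_ox,B,decay
300,2.97341778858695e-06,M8B,WT_ox,B,decay
320,4.26629451214345e-06,M8B,WT_ox,B,decay
340,1.44141776102925e-06,M8B,WT_ox,B,decay
360,1.09782657205492e-06,M8B,WT_ox,B,decay
0,3.30875124933389e-05,M5A,WT_ox,A,decay
20,1.21845734974792e-05,M5A,WT_ox,A,decay
40,2.79294170218255e-06,M5A,WT_ox,A,decay
60,2.60626825002595e-06,M5A,WT_ox,A,decay
80,1.62519903984655e-07,M5A,WT_ox,A,decay
100,-8.57592310730685e-07,M5A,WT_ox,A,decay
120,-5.80218952755948e-07,M5A,WT_ox,A,decay
140,5.12196030262367e-08,M5A,WT_ox,A,decay
160,9.08875034873016e-07,M5A,WT_ox,A,decay
180,1.54041054511419e-07,M5A,WT_ox,A,decay
200,7.36612171501166e-07,M5A,WT_ox,A,decay
220,7.38264054174511e-08,M5A,WT_ox,A,decay
240,-1.05360627263266e-06,M5A,WT_ox,A,decay
260,9.78952591540468e-07,M5A,WT_ox,A,decay
280,9.90841960186808e-07,M5A,WT_ox,A,decay
300,-7.44030387567948e-07,M5A,WT_ox,A,decay
320,-1.90413101706055e-06,M5A,WT_ox,A,decay
340,-8.61694389611063e-08,M5A,WT_ox,A,decay
360,7.05671670887123e-07,M5A,WT_ox,A,decay
0,-9.40682293422402e-07,h2bA,WT_ox,A,buildup
20,2.20215284157193e-05,h2bA,WT_ox,A,buildup
40,2.96435583150851e-05,h2bA,WT_ox,A,buildup
60,3.29034832967305e-05,h2bA,WT_ox,A,buildup
80,3.44018807368524e-05,h2bA,WT_ox,A,buildup
100,3.39320659112967e-05,h2bA,WT_ox,A,buildup
120,3.32920171960353e-05,h2bA,WT_ox,A,buildup
140,3.41380469392622e-05,h2bA,WT_ox,A,buildup
160,3.39154547507925e-05,h2bA,WT_ox,A,buildup
180,3.4904497342685e-05,h2bA,WT_ox,A,buildup
200,3.51514079577404e-05,h2bA,WT_ox,A,buildup
220,3.43705656928971e-05,h2bA,WT_ox,A,buildup
240,3.64328731538788e-05,h2bA,WT_ox,A,buildup
260,3.49947737447012e-05,h2bA,WT_ox,A,buildup
280,3.32069683068504e-05,h2bA,WT_ox,A,buildup
300,3.47460115830931e-05,h2bA,WT_ox,A,buildup
320,3.49648814087128e-05,h2bA,WT_ox,A,buildup
340,3.45671714272262e-05,h2bA,WT_ox,A,buildup
360,3.51718019680992e-05,h2bA,WT_ox,A,buildup
0,-8.50149794651569e-07,m3B/m8B,WT_ox,B,buildup
20,1.22897301937216e-05,m3B/m8B,WT_ox,B,buildup
40,2.189945451311e-05,m3B/m8B,WT_ox,B,buildup
60,2.84586846781323e-05,m3B/m8B,WT_ox,B,buildup
80,3.59508419606142e-05,m3B/m8B,WT_ox,B,buildup
100,4.09182238362518e-05,m3B/m8B,WT_ox,B,buildup
120,4.49407717689648e-05,m3B/m8B,WT_ox,B,buildup
140,4.891143464636e-05,m3B/m8B,WT_ox,B,buildup
160,5.10779971149428e-05,m3B/m8B,WT_ox,B,buildup
180,5.36149013913644e-05,m3B/m8B,WT_ox,B,buildup
200,5.48292909380012e-05,m3B/m8B,WT_ox,B,buildup
220,5.70548080885945e-05,m3B/m8B,WT_ox,B,buildup
240,5.89764987737898e-05,m3B/m8B,WT_ox,B,buildup
260,5.81559625715079e-05,m3B/m8B,WT_ox,B,buildup
280,6.01169201681719e-05,m3B/m8B,WT_ox,B,buildup
300,6.11920142002221e-05,m3B/m8B,WT_ox,B,buildup
320,6.02202410346121e-05,m3B/m8B,WT_ox,B,buildup
340,6.04477293562267e-05,m3B/m8B,WT_ox,B,buildup
360,6.17711021445157e-05,m3B/m8B,WT_ox,B,buildup
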